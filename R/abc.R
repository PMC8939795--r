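#' Parameter prior specification
#'
#' Per-parameter prior families for the sequential ABC fitter: log-normal
#' (positivity-respecting; used for gains, time constants and connection
#' weights) or uniform (used for delays).
#'
#' @param name parameter names.
#' @param dist `"lognormal"` or `"uniform"` per parameter.
#' @param p1 meanlog (lognormal) or lower bound (uniform).
#' @param p2 sdlog (lognormal) or upper bound (uniform).
#' @return Data frame of class `cbgt_prior`.
#' @export
prior_spec <- function(name, dist, p1, p2) {
  dist <- match.arg(dist, c("lognormal", "uniform"), several.ok = TRUE)
  if (length(dist) == 1L) dist <- rep(dist, length(name))
  out <- data.frame(name = name, dist = dist, p1 = p1, p2 = p2,
                    stringsAsFactors = FALSE)
  bad <- out$dist == "uniform" & out$p1 <= 0
  if (any(bad & grepl("delay", out$name)))
    stop("delay priors must have positive support")
  structure(out, class = c("cbgt_prior", "data.frame"))
}

#' Default priors around a circuit's values
#'
#' Log-normal priors (sdlog 0.5) centred on the shipped values for
#' multiplicative parameters; uniform 1-10 ms priors for delays when
#' requested.
#'
#' @param centre named numeric vector of central values.
#' @param sdlog spread of the log-normal priors (default 0.5).
#' @return A [prior_spec()] object.
#' @export
default_priors <- function(centre, sdlog = 0.5) {
  is_delay <- grepl("delay", names(centre))
  prior_spec(names(centre),
             ifelse(is_delay, "uniform", "lognormal"),
             ifelse(is_delay, 0.001, log(centre)),
             ifelse(is_delay, 0.010, sdlog))
}

draw_prior <- function(prior, n) {
  th <- vapply(seq_len(nrow(prior)), function(k) {
    if (prior$dist[k] == "lognormal")
      stats::rlnorm(n, prior$p1[k], prior$p2[k])
    else stats::runif(n, prior$p1[k], prior$p2[k])
  }, numeric(n))
  if (n == 1L) th <- matrix(th, 1L)
  colnames(th) <- prior$name
  th
}

#' Distance between feature sets
#'
#' Mean squared error over the concatenated features (spectra plus any NPD
#' components) of two [feature_set()] objects on matching grids.
#'
#' @param fs_sim,fs_target `cbgt_features` objects.
#' @return Non-negative scalar; 0 for identical features.
#' @export
feature_distance <- function(fs_sim, fs_target) {
  if (!isTRUE(all.equal(fs_sim$freqs, fs_target$freqs)))
    stop("feature frequency grids do not match")
  flat <- function(f) {
    c(as.numeric(f$psd),
      unlist(f$npd, use.names = FALSE))
  }
  a <- flat(fs_sim); b <- flat(fs_target)
  if (length(a) != length(b)) stop("feature structures do not match")
  mean((a - b)^2)
}

perturb <- function(th, prior, scale) {
  for (k in seq_len(nrow(prior))) {
    if (prior$dist[k] == "lognormal") {
      th[, k] <- exp(log(th[, k]) + stats::rnorm(nrow(th), 0, scale[k]))
    } else {
      th[, k] <- th[, k] + stats::rnorm(nrow(th), 0, scale[k])
      th[, k] <- pmin(pmax(th[, k], prior$p1[k]), prior$p2[k])
    }
  }
  th
}

marginal_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Sequential approximate Bayesian computation
#'
#' Likelihood-free fit of simulator parameters to target features. Each
#' generation simulates every particle, pools the new draws with the
#' previous survivors, keeps the best fraction `q` (which defines the
#' adaptively shrinking error threshold), and resamples + perturbs the
#' survivors (Gaussian kernel at half the survivors' standard deviation,
#' in log space for log-normal parameters). Iteration stops when the
#' relative threshold improvement falls below `grad_tol` or after
#' `max_gens` generations.
#'
#' @param simulator `function(theta, seed)` returning a `cbgt_features`
#'   object; `theta` is a named numeric vector.
#' @param target `cbgt_features` target (e.g. from [gen_abc_target()] or
#'   read from CSV).
#' @param prior a [prior_spec()] object.
#' @param n_particles particles per generation (default 200; >= 50 for a
#'   meaningful posterior).
#' @param max_gens maximum generations (default 10).
#' @param q survivor fraction per generation (default 0.3).
#' @param grad_tol relative threshold-improvement stopping tolerance
#'   (default 0.05; `Inf` stops after one generation).
#' @param seed integer seed governing all draws.
#' @return Object of class `cbgt_posterior`: `particles` (survivor draws),
#'   `distances`, `schedule` (threshold sequence), `map_estimate` (mode of
#'   the marginal posteriors), `converged`, `n_gens`.
#' @export
sequential_abc <- function(simulator, target, prior, n_particles = 200,
                           max_gens = 10, q = 0.3, grad_tol = 0.05,
                           seed = 1) {
  if (n_particles < 50)
    warning("n_particles < 50: posterior summaries will be unstable")
  set.seed(seed)
  seed_pool <- sample.int(.Machine$integer.max - 1L, n_particles * max_gens)
  n_keep <- max(2L, ceiling(q * n_particles))
  sim_d <- function(th_row, sd) {
    f <- tryCatch(simulator(th_row, sd), error = function(e) NULL)
    if (is.null(f)) return(Inf)
    feature_distance(f, target)
  }
  theta <- draw_prior(prior, n_particles)
  d <- vapply(seq_len(n_particles), function(i)
    sim_d(stats::setNames(theta[i, ], prior$name), seed_pool[i]), 1)
  if (all(!is.finite(d))) stop("all particles diverged in generation 1")
  ord <- order(d)[seq_len(n_keep)]
  surv <- theta[ord, , drop = FALSE]
  surv_d <- d[ord]
  schedule <- max(surv_d)
  converged <- FALSE
  g <- 1L
  if (is.infinite(grad_tol) && grad_tol > 0) converged <- TRUE
  while (!converged && g < max_gens) {
    g <- g + 1L
    scale <- vapply(seq_len(nrow(prior)), function(k) {
      x <- if (prior$dist[k] == "lognormal") log(surv[, k]) else surv[, k]
      max(stats::sd(x) / 2, 1e-8)
    }, 1)
    idx <- sample.int(nrow(surv), n_particles, replace = TRUE)
    theta <- perturb(surv[idx, , drop = FALSE], prior, scale)
    d <- vapply(seq_len(n_particles), function(i)
      sim_d(stats::setNames(theta[i, ], prior$name),
            seed_pool[(g - 1L) * n_particles + i]), 1)
    pool_th <- rbind(surv, theta)
    pool_d <- c(surv_d, d)
    if (all(!is.finite(pool_d)))
      stop("all particles diverged in generation ", g)
    ord <- order(pool_d)[seq_len(n_keep)]
    surv <- pool_th[ord, , drop = FALSE]
    surv_d <- pool_d[ord]
    eps <- max(surv_d)
    improvement <- (schedule[length(schedule)] - eps) /
      schedule[length(schedule)]
    schedule <- c(schedule, eps)
    if (improvement < grad_tol) { converged <- TRUE; break }
  }
  map <- vapply(seq_len(nrow(prior)), function(k) {
    if (prior$dist[k] == "lognormal") exp(marginal_mode(log(surv[, k])))
    else marginal_mode(surv[, k])
  }, 1)
  names(map) <- prior$name
  structure(list(particles = surv, distances = surv_d, schedule = schedule,
                 map_estimate = map, converged = converged, n_gens = g,
                 prior = prior),
            class = "cbgt_posterior")
}

#' @export
print.cbgt_posterior <- function(x, ...) {
  cat(sprintf("<cbgt_posterior> %d survivors after %d generation(s)%s\n",
              nrow(x$particles), x$n_gens,
              if (x$converged) " (converged)" else ""))
  cat("  threshold schedule:",
      paste(signif(x$schedule, 4), collapse = " -> "), "\n")
  cat("  MAP:", paste(sprintf("%s=%.4g", names(x$map_estimate),
                              x$map_estimate), collapse = ", "), "\n")
  invisible(x)
}

#' Approximate model evidence
#'
#' Marginal probability estimate for model comparison: parameters are drawn
#' from the posterior, the model is re-simulated, and the evidence is the
#' fraction of draws whose feature distance to the target falls below the
#' common threshold `eps_star`.
#'
#' @param posterior a [sequential_abc()] result.
#' @param simulator the `function(theta, seed)` used in the fit.
#' @param target the target features.
#' @param eps_star distance threshold common across compared models.
#' @param n_draws posterior draws (default 50; < 20 warns).
#' @param seed integer seed.
#' @return Probability in `[0, 1]`.
#' @export
model_evidence <- function(posterior, simulator, target, eps_star,
                           n_draws = 50, seed = 1) {
  if (n_draws < 20) warning("n_draws < 20: evidence estimate unstable")
  if (!is.finite(eps_star) && eps_star > 0) return(1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  idx <- sample.int(nrow(posterior$particles), n_draws, replace = TRUE)
  hits <- vapply(seq_len(n_draws), function(i) {
    th <- stats::setNames(posterior$particles[idx[i], ],
                          colnames(posterior$particles))
    f <- tryCatch(simulator(th, seeds[i]), error = function(e) NULL)
    if (is.null(f)) return(FALSE)
    feature_distance(f, target) < eps_star
  }, TRUE)
  mean(hits)
}
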