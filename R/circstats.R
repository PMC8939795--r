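#' Circular mean and standard deviation
#'
#' Mean direction is the argument of the resultant vector; the circular
#' standard deviation is `sqrt(-2 log(Rbar))` with `Rbar` the mean resultant
#' length. A zero resultant leaves the mean direction undefined.
#'
#' @param angles radians.
#' @return List with `mean` (radians, `NA` with a warning when the resultant
#'   vanishes), `sd` (radians), `rbar` (mean resultant length), `n`.
#' @export
circular_mean_sd <- function(angles) {
  stopifnot(length(angles) >= 1)
  r <- mean(exp(1i * angles))
  rbar <- Mod(r)
  if (rbar < .Machine$double.eps^0.5) {
    warning("zero resultant: circular mean undefined")
    return(list(mean = NA_real_, sd = Inf, rbar = rbar, n = length(angles)))
  }
  list(mean = Arg(r), sd = sqrt(-2 * log(rbar)), rbar = rbar,
       n = length(angles))
}

# maximum-likelihood von Mises concentration from Rbar (Fisher 1993 approx.)
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) return(2 * rbar + rbar^3 + 5 * rbar^5 / 6)
  if (rbar < 0.85) return(-0.4 + 1.39 * rbar + 0.43 / (1 - rbar))
  1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
}

#' Rayleigh test of circular uniformity
#'
#' Statistic `z = n * Rbar^2` with the standard large-sample p-value
#' approximation.
#'
#' @param angles radians (n >= 2).
#' @return List with `z`, `p`, `rbar`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  stopifnot(n >= 2)
  rbar <- Mod(mean(exp(1i * angles)))
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z = z, p = max(0, min(1, p)), rbar = rbar, n = n)
}

#' Watson-Williams test for equal mean directions
#'
#' Multi-sample circular analogue of the one-way ANOVA F test, with the
#' standard concentration correction factor `1 + 3/(8 kappa)`. Valid for
#' reasonably concentrated samples; a warning is emitted when the pooled
#' mean resultant length is below 0.45.
#'
#' @param groups list of numeric vectors of angles (radians), each n >= 2.
#' @return List with `F`, `df` (numerator, denominator), `p`, `kappa`.
#' @export
watson_williams <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 angles")
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  p <- length(groups)
  Rs <- vapply(groups, function(g) Mod(sum(exp(1i * g))), 1)
  R <- Mod(sum(exp(1i * unlist(groups))))
  rw <- sum(Rs) / N
  if (rw < 0.45)
    warning("low concentration (pooled Rbar < 0.45): test may be invalid")
  kappa <- kappa_from_rbar(rw)
  K <- 1 + 3 / (8 * kappa)
  if (N - sum(Rs) < .Machine$double.eps^0.5 * N) {
    # perfectly concentrated groups: F degenerates to 0 (equal means) or Inf
    Fstat <- if (sum(Rs) - R < .Machine$double.eps^0.5 * N) 0 else Inf
  } else {
    Fstat <- K * ((N - p) * (sum(Rs) - R)) / ((p - 1) * (N - sum(Rs)))
  }
  df <- c(p - 1, N - p)
  pval <- stats::pf(Fstat, df[1], df[2], lower.tail = FALSE)
  list(F = Fstat, df = df, p = pval, kappa = kappa)
}

#' Cluster-based permutation test for time-locked traces
#'
#' Compares two sets of traces (e.g. burst-locked envelopes under two
#' conditions) with a pointwise two-sample t-statistic, clusters contiguous
#' samples exceeding the two-sided alpha threshold, sums the t-values within
#' each cluster (cluster mass), and evaluates mass against a label
#' permutation null built from the maximum absolute cluster mass of each
#' permutation. Clusters shorter than `min_duration` are excluded and at
#' most `max_reported` clusters (largest masses) are reported.
#'
#' @param test_traces,ref_traces matrices, traces in rows, equal column
#'   counts; at least two traces each.
#' @param fs sampling rate of the trace time axis, Hz.
#' @param n_perm permutations (default 500; < 100 warns).
#' @param alpha two-sided cluster-forming and inference level (default 0.05).
#' @param min_duration minimum reported cluster duration, seconds (0.02).
#' @param max_reported maximum number of clusters reported (5).
#' @return Object of class `cbgt_clusters`: data frame `clusters` with
#'   `start`, `end` (seconds), `mass`, `p`, plus the call parameters.
#' @export
cluster_permutation <- function(test_traces, ref_traces, fs, n_perm = 500,
                                alpha = 0.05, min_duration = 0.02,
                                max_reported = 5) {
  test_traces <- as.matrix(test_traces); ref_traces <- as.matrix(ref_traces)
  stopifnot(ncol(test_traces) == ncol(ref_traces),
            nrow(test_traces) >= 2, nrow(ref_traces) >= 2)
  if (n_perm < 100) warning("n_perm < 100: unstable cluster p-values")
  n1 <- nrow(test_traces); n2 <- nrow(ref_traces)
  all_tr <- rbind(test_traces, ref_traces)
  tvec <- function(idx1) {
    x <- all_tr[idx1, , drop = FALSE]
    y <- all_tr[-idx1, , drop = FALSE]
    m1 <- colMeans(x); m2 <- colMeans(y)
    v1 <- colSums((x - rep(m1, each = nrow(x)))^2) / (nrow(x) - 1)
    v2 <- colSums((y - rep(m2, each = nrow(y)))^2) / (nrow(y) - 1)
    (m1 - m2) / sqrt(v1 / nrow(x) + v2 / nrow(y))
  }
  tcrit <- stats::qt(1 - alpha / 2, n1 + n2 - 2)
  min_len <- ceiling(min_duration * fs)
  # the duration exclusion is applied to the permutation null as well, so the
  # reported cluster p-values stay calibrated under the exclusion rule
  clusters_of <- function(tv) {
    supra <- abs(tv) > tcrit
    if (!any(supra)) return(NULL)
    r <- rle(supra)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    data.frame(i0 = starts[keep], i1 = ends[keep],
               mass = mapply(function(a, b) sum(tv[a:b]),
                             starts[keep], ends[keep]))
  }
  obs <- clusters_of(tvec(seq_len(n1)))
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n1 + n2, n1)
    cl <- clusters_of(tvec(idx))
    null_max[p] <- if (is.null(cl)) 0 else max(abs(cl$mass))
  }
  out <- data.frame(start = numeric(0), end = numeric(0),
                    mass = numeric(0), p = numeric(0))
  if (!is.null(obs)) {
    obs$start <- (obs$i0 - 1) / fs
    obs$end <- obs$i1 / fs
    if (nrow(obs)) {
      obs$p <- vapply(obs$mass, function(m)
        (1 + sum(null_max >= abs(m))) / (n_perm + 1), 1)
      obs <- obs[order(-abs(obs$mass)), ]
      obs <- utils::head(obs, max_reported)
      out <- obs[, c("start", "end", "mass", "p")]
      rownames(out) <- NULL
    }
  }
  structure(list(clusters = out, alpha = alpha, n_perm = n_perm,
                 min_duration = min_duration, max_reported = max_reported,
                 null_max = null_max),
            class = "cbgt_clusters")
}

#' @export
print.cbgt_clusters <- function(x, ...) {
  cat(sprintf("<cbgt_clusters> %d cluster(s) reported, %d with p <= %g\n",
              nrow(x$clusters), sum(x$clusters$p <= x$alpha), x$alpha))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
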