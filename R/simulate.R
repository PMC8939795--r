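#' Sigmoid activation (population output rate)
#'
#' Mean output rate of a population as a function of its average membrane
#' voltage, `1 / (1 + exp(-slope * v))`, bounded in (0, 1) and strictly
#' increasing in `v`. The slope parameter models the spread of firing
#' thresholds within the population.
#'
#' @param v voltage (vectorized).
#' @param slope sigmoid slope parameter (> 0).
#' @return Rate in (0, 1).
#' @export
#' @examples
#' sigmoid_rate(0, 3)    # 0.5 by symmetry
#' sigmoid_rate(1, 2)    # 0.880797
sigmoid_rate <- function(v, slope) {
  if (any(!is.finite(v))) stop("non-finite voltage")
  if (any(slope <= 0)) stop("slope must be > 0")
  1 / (1 + exp(-slope * v))
}

#' Delayed afferent drive to a source
#'
#' Total input to a target source at time `t`: the sum over all sources of
#' the connection weight times the sigmoid output of the presynaptic source
#' evaluated at the delayed voltage `V_m(t - D[n, m])`. Only strictly past
#' voltages are read.
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param history matrix of population voltages (rows = time steps at `dt`,
#'   columns = the nine populations in canonical order); row `k` holds the
#'   state at time `k * dt`, and the last row is the state at `t`.
#' @param t current time in seconds (must equal `nrow(history) * dt`).
#' @param target source index (1-6) or label.
#' @param dt integration step in seconds.
#' @return Scalar drive to the target source's input population.
#' @export
afferent_drive <- function(circuit, history, t, target, dt) {
  src <- cbgt_sources()
  if (is.character(target)) target <- match(target, src)
  stopifnot(target %in% 1:6)
  m <- circuit_matrices(circuit)
  n <- nrow(history)
  if (abs(n * dt - t) > dt / 2)
    stop("t must correspond to the last row of history")
  cons <- circuit$inter[circuit$inter$to == src[target], , drop = FALSE]
  if (nrow(cons) == 0L) return(0)
  dmax <- max(cons$delay)
  if (n * dt < dmax)
    stop("history shorter than the maximum afferent delay")
  drive <- 0
  pops <- circuit$populations
  for (k in seq_len(nrow(cons))) {
    pfrom <- circuit$output_map[[cons$from[k]]]
    j <- match(pfrom, pops$id)
    lag <- max(1L, as.integer(round(cons$delay[k] / dt)))
    vdel <- if (n - lag >= 1) history[n - lag, j] else 0
    w <- pop_sign(circuit, pfrom) * cons$weight[k]
    drive <- drive + w * sigmoid_rate(vdel, pops$slope[j])
  }
  drive
}

#' One Euler-Maruyama step of the second-order neural mass dynamics
#'
#' Advances each population's `(v, vdot)` pair by one step of
#' `vddot = (H/tau) p - (2/tau) vdot - v / tau^2`, where `p` is the synaptic
#' drive (afferents plus any injected stimulation) plus the scaled intrinsic
#' input; the stochastic term enters the rate equation scaled by `sqrt(dt)`.
#' This is the reference (pure R) form of the update performed by the
#' compiled integrator.
#'
#' @param state list with numeric vectors `v` and `vdot` (one entry per
#'   population).
#' @param drives per-population deterministic input (afferent + stimulation).
#' @param noise_draw per-population stochastic input draw, with standard
#'   deviation equal to the population's `noise_sd`.
#' @param dt step size in seconds (> 0).
#' @param circuit a [cbgt_circuit()] object supplying `tau`, `gain`, `slope`
#'   and `noise_scale`.
#' @return Updated state list.
#' @export
neural_mass_step <- function(state, drives, noise_draw, dt, circuit) {
  if (dt <= 0) stop("dt must be > 0")
  p <- circuit$populations
  if (any(!is.finite(c(state$v, state$vdot, drives, noise_draw))))
    stop("non-finite inputs")
  a <- p$gain / p$tau
  vnew <- state$v + dt * state$vdot
  vdnew <- state$vdot +
    dt * (a * drives - (2 / p$tau) * state$vdot - state$v / p$tau^2) +
    a * p$noise_scale * noise_draw * sqrt(dt)
  list(v = vnew, vdot = vdnew)
}

#' Simulation configuration
#'
#' @param duration total simulated time in seconds (including burn-in).
#' @param dt integration step in seconds (default 0.5 ms).
#' @param burn_in initial transient discarded from all outputs, seconds.
#' @param seed integer seed; all stochasticity flows through it.
#' @param out_rate observation rate of the returned signals, Hz.
#' @return A list of class `cbgt_sim_config`.
#' @export
sim_config <- function(duration, dt = 5e-4, burn_in = 2, seed = 1,
                       out_rate = 250) {
  if (duration <= burn_in) stop("duration must exceed burn_in")
  decim <- (1 / dt) / out_rate
  if (abs(decim - round(decim)) > 1e-9)
    stop("out_rate must divide the integration rate 1/dt")
  structure(list(duration = duration, dt = dt, burn_in = burn_in,
                 seed = as.integer(seed), out_rate = out_rate),
            class = "cbgt_sim_config")
}

#' Labelled multichannel time series
#'
#' @param data channels x samples numeric matrix.
#' @param labels channel labels (unique).
#' @param fs sampling rate in Hz.
#' @param meta provenance list (config, seed, ...).
#' @return Object of class `cbgt_ts`.
#' @export
ts_set <- function(data, labels, fs, meta = list()) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(labels), !anyDuplicated(labels))
  if (any(!is.finite(data))) stop("non-finite samples in time series")
  rownames(data) <- labels
  structure(list(data = data, labels = labels, fs = fs, meta = meta),
            class = "cbgt_ts")
}

#' @export
print.cbgt_ts <- function(x, ...) {
  cat(sprintf("<cbgt_ts> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a time series set
#' @param ts a `cbgt_ts` object.
#' @param label channel label.
#' @return Numeric vector.
#' @export
ts_channel <- function(ts, label) {
  i <- match(label, ts$labels)
  if (is.na(i)) stop("no channel named ", label)
  as.numeric(ts$data[i, ])
}

# --- internal integration plumbing ------------------------------------------

sim_prepare <- function(circuit, config) {
  validate_circuit(circuit)
  m <- circuit_matrices(circuit)
  dt <- config$dt
  nzd <- m$D[m$W != 0]
  if (length(nzd) && dt > min(nzd) / 2)
    stop("dt must be at most half the smallest connection delay")
  dsteps <- matrix(0L, 9, 9)
  dsteps[m$W != 0] <- pmax(1L, as.integer(round(m$D[m$W != 0] / dt)))
  p <- circuit$populations
  n_raw <- as.integer(round(config$duration / dt))
  list(W = m$W, dsteps = dsteps, tau = p$tau, gain = p$gain, slope = p$slope,
       csd = p$noise_scale * p$noise_sd, n_raw = n_raw,
       n_burn = as.integer(round(config$burn_in / dt)),
       decim = as.integer(round((1 / dt) / config$out_rate)))
}

sim_noise <- function(config, n_raw) {
  set.seed(config$seed)
  matrix(stats::rnorm(n_raw * 9L), n_raw, 9L)
}

# run the compiled integrator over [from, from + nsteps) raw steps, in place
sim_run_chunk <- function(prep, vbuf, state, from, nsteps, noise, stim,
                          stim_pop, dt) {
  diag <- integer(2)
  status <- .integrate_chunk(vbuf, state$v, state$vdot, as.integer(from),
                             as.integer(nsteps), noise, stim,
                             as.integer(stim_pop) - 1L, prep$dsteps, prep$W,
                             prep$tau, prep$gain, prep$slope, prep$csd,
                             dt, 1e5, diag)
  if (status != 0L)
    stop(sprintf("unstable trajectory: population %s diverged at t = %.3f s",
                 cbgt_populations()[diag[1]], diag[2] * dt))
  invisible(state)
}

# anti-alias zero-phase FIR low-pass then downsample; drops burn-in first
sim_finalize <- function(vbuf, circuit, config, prep, meta) {
  obs <- match(circuit$observation_map, circuit$populations$id)
  raw <- vbuf[, obs, drop = FALSE]
  cutoff <- 0.8 * config$out_rate / (1 / config$dt)
  ord <- max(64L, 2L * ceiling(2 / cutoff))   # keep the transition band sharp
  b <- signal::fir1(ord, cutoff)
  filt <- apply(raw, 2, function(x) as.numeric(signal::filtfilt(b, x)))
  keep <- seq.int(prep$n_burn + prep$decim, prep$n_raw, by = prep$decim)
  data <- t(filt[keep, , drop = FALSE])
  # controller-equivalent view: plain subsampling, no anti-alias filter
  sub <- t(raw[keep, , drop = FALSE])
  rownames(sub) <- cbgt_sources()
  out <- ts_set(data, cbgt_sources(), config$out_rate, meta)
  out$subsampled <- sub
  out
}

#' Simulate the circuit
#'
#' Integrates the nine coupled second-order stochastic delay differential
#' equations with the Euler-Maruyama scheme at `config$dt`, discards the
#' burn-in, and decimates the observed population voltages (one per source;
#' M2 is observed at the superficial pyramidal layer) to `config$out_rate`
#' with a zero-phase FIR anti-alias low-pass. All noise is drawn up-front
#' from `config$seed`, so runs are reproducible and a stimulated run can
#' reuse the identical noise realization as its baseline (pass `noise`).
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param config a [sim_config()] object.
#' @param controller optional [controller_config()]; if supplied the run is
#'   dispatched to the closed-loop driver [simulate_stimulation()] and a
#'   stimulation record is attached to the result.
#' @param noise optional pre-drawn standard normal noise matrix
#'   (raw steps x 9); defaults to a fresh draw from `config$seed`.
#' @return A [ts_set()] with channels M2, STR, GPe, STN, GPi, Thal. The
#'   element `subsampled` holds the plain-subsampled 250 Hz view the on-line
#'   controller senses. With a controller, element `stim_record` holds the
#'   [stimulation record][simulate_stimulation].
#' @export
#' @examples
#' sim <- simulate_cbgt(cbgt_circuit(), sim_config(duration = 6, seed = 1))
#' sim
simulate_cbgt <- function(circuit, config, controller = NULL, noise = NULL) {
  if (!is.null(controller))
    return(simulate_stimulation(circuit, config, controller, noise = noise))
  prep <- sim_prepare(circuit, config)
  if (is.null(noise)) noise <- sim_noise(config, prep$n_raw)
  stopifnot(nrow(noise) >= prep$n_raw)
  vbuf <- matrix(0, prep$n_raw, 9L)
  state <- list(v = numeric(9), vdot = numeric(9))
  stim <- numeric(prep$n_raw)
  sim_run_chunk(prep, vbuf, state, 0L, prep$n_raw, noise, stim, 0L, config$dt)
  sim_finalize(vbuf, circuit, config, prep,
               meta = list(seed = config$seed, config = unclass(config)))
}
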