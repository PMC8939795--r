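#' Von Mises random angles
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' circle.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(wrap_phase(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  wrap_phase(out + mu)
}

#' Von Mises concentration for a target mean resultant length
#'
#' Solves `I1(kappa)/I0(kappa) = plv_target` numerically.
#'
#' @param plv_target target PLV in `[0, 1)` (1 maps to `Inf`).
#' @return Concentration parameter.
#' @export
kappa_for_plv <- function(plv_target) {
  stopifnot(plv_target >= 0, plv_target <= 1)
  if (plv_target == 0) return(0)
  if (plv_target >= 0.9999) return(Inf)
  ratio <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) ratio(k) - plv_target, c(1e-6, 5000))$root
}

# power-law (1/f) background noise, unit variance
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  W <- W / f^(alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

#' Bursty band-limited oscillation with known burst intervals
#'
#' Amplitude-modulated sinusoid at the band centre: a constant baseline
#' envelope with boxcar bursts (smoothed by a short moving average) plus a
#' 1/f background at the requested signal-to-noise ratio. The generating
#' burst intervals are returned as ground truth.
#'
#' @param fs sampling rate, Hz (default 250).
#' @param duration seconds.
#' @param band `c(low, high)` Hz; the carrier sits at the centre.
#' @param burst_rate mean burst rate, Hz (bursts per second; 0 for none).
#' @param burst_len burst duration, seconds.
#' @param snr_db ratio of within-burst carrier power to background power,
#'   dB (`Inf` for noiseless).
#' @param base_amp envelope outside bursts (relative to burst amplitude 1).
#' @param seed integer seed.
#' @return List with `ts` (single-channel [ts_set()], label `"STN"`),
#'   `truth` (data frame `onset`/`offset` seconds), `carrier_freq`.
#' @export
gen_bursty_oscillation <- function(fs = 250, duration = 30, band = c(14, 21),
                                   burst_rate = 0.4, burst_len = 0.4,
                                   snr_db = 10, base_amp = 0.25, seed = 1) {
  set.seed(seed)
  n <- round(fs * duration)
  t <- seq_len(n) / fs
  f0 <- mean(band)
  env <- rep(base_amp, n)
  truth <- data.frame(onset = numeric(0), offset = numeric(0))
  if (burst_rate > 0) {
    pos <- 0.5
    while (pos + burst_len < duration - 0.5) {
      gap <- stats::rexp(1, burst_rate)
      onset <- pos + gap
      if (onset + burst_len > duration - 0.5) break
      truth <- rbind(truth, data.frame(onset = onset,
                                       offset = onset + burst_len))
      i0 <- round(onset * fs) + 1L
      i1 <- min(n, round((onset + burst_len) * fs))
      env[i0:i1] <- 1
      pos <- onset + burst_len + 0.2   # enforce separation
    }
  }
  k <- max(1L, round(0.05 * fs))
  env <- stats::filter(c(rep(env[1], k), env, rep(env[n], k)),
                       rep(1 / k, k), sides = 2)
  env <- as.numeric(env)[(k + 1):(k + n)]
  x <- env * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
  if (is.finite(snr_db)) {
    noise_sd <- sqrt((1 / 2) / 10^(snr_db / 10))
    x <- x + noise_sd * pink_noise(n)
  }
  ts <- ts_set(matrix(x, 1), "STN", fs,
               meta = list(seed = seed, kind = "bursty_oscillation",
                           config = list(burn_in = 0)))
  list(ts = ts, truth = truth, carrier_freq = f0)
}

#' Coupled signal pair with known PLV and phase lag
#'
#' A common band-limited phase process (frequency-wandering sinusoid)
#' drives both channels; channel 2's phase equals channel 1's plus
#' `phase_lag` plus i.i.d. von Mises jitter whose concentration solves
#' `I1(kappa)/I0(kappa) = plv_target`, so the expected PLV of the returned
#' ground-truth phases equals `plv_target` analytically.
#'
#' @param fs sampling rate, Hz.
#' @param duration seconds.
#' @param band `c(low, high)` Hz.
#' @param plv_target target PLV in `[0, 1]` (1 selects the zero-jitter
#'   branch).
#' @param phase_lag channel-1-minus-channel-2 phase lag, radians.
#' @param seed integer seed.
#' @return List with `ts` (two channels `"A"`, `"B"`), `phases` (matrix of
#'   ground-truth phases), `plv_target`, `kappa`, `phase_lag`.
#' @export
gen_coupled_pair <- function(fs = 250, duration = 30, band = c(14, 21),
                             plv_target = 0.8, phase_lag = 0, seed = 1) {
  set.seed(seed)
  n <- round(fs * duration)
  f0 <- mean(band)
  # smoothly wandering instantaneous frequency within the band
  fdev <- stats::filter(stats::rnorm(n), rep(1 / 50, 50), circular = TRUE)
  fdev <- as.numeric(fdev) / stats::sd(fdev) * diff(band) / 6
  phi1 <- wrap_phase(cumsum(2 * pi * (f0 + fdev) / fs))
  kappa <- kappa_for_plv(plv_target)
  jit <- if (is.infinite(kappa)) numeric(n) else rvonmises(n, 0, kappa)
  phi2 <- wrap_phase(phi1 - phase_lag + jit)
  x <- rbind(A = sin(phi1), B = sin(phi2))
  ts <- ts_set(x, c("A", "B"), fs,
               meta = list(seed = seed, kind = "coupled_pair",
                           config = list(burn_in = 0)))
  list(ts = ts, phases = cbind(A = phi1, B = phi2),
       plv_target = plv_target, kappa = kappa, phase_lag = phase_lag)
}

#' Synthetic ABC fitting target from the model itself
#'
#' Simulates the circuit at known parameters and returns the feature set
#' (spectra plus optional NPD pairs) to be used as a fitting target, along
#' with the generating truth.
#'
#' @param circuit a [cbgt_circuit()] object (already carrying the desired
#'   true parameters).
#' @param duration simulated seconds after burn-in (default 30).
#' @param seed integer seed.
#' @param pairs NPD channel pairs (default `list(c("M2", "STN"))`).
#' @param channels channels whose spectra enter the features (default all).
#' @return List with `features` (`cbgt_features`), `circuit`.
#' @export
gen_abc_target <- function(circuit, duration = 30, seed = 1,
                           pairs = list(c("M2", "STN")), channels = NULL) {
  sim <- simulate_cbgt(circuit, sim_config(duration = duration + 2,
                                           seed = seed))
  if (!is.null(channels))
    sim <- ts_set(sim$data[channels, , drop = FALSE], channels, sim$fs,
                  sim$meta)
  list(features = feature_set(sim, pairs = pairs), circuit = circuit)
}
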