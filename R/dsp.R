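# shared signal-processing primitives (internal)

# analytic signal via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# zero-phase Butterworth band-pass
bp_filtfilt <- function(x, band, fs, order = 4) {
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return Wrapped angles.
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# wrap-safe phase difference phi1 - phi2
phase_diff <- function(phi1, phi2) Arg(exp(1i * phi1) * exp(-1i * phi2))

# linear-interpolation percentile (R default type 7)
pct_threshold <- function(x, pct) unname(stats::quantile(x, pct / 100, type = 7))
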