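#' Preprocess a time-series set into artifact-rejected 1 s epochs
#'
#' Mirrors the standard field pipeline: per-channel mean subtraction, a
#' zero-lag two-pass FIR band-pass at 4-100 Hz, z-scoring to unit variance,
#' division into non-overlapping 1 s epochs, and rejection of any epoch in
#' which any channel's absolute z-value exceeds `artifact_z` (epochs are
#' dropped jointly across channels so cross-spectra stay aligned).
#'
#' @param ts a [ts_set()] object (fs = 250 Hz in the standard analyses).
#' @param artifact_z rejection threshold in z units (default 6).
#' @param band band-pass edges in Hz (default `c(4, 100)`).
#' @return List of class `cbgt_epochs`: `epochs` (array
#'   `n_epochs x epoch_len x n_channels`), `labels`, `fs`, `n_dropped`.
#' @export
preprocess_epochs <- function(ts, artifact_z = 6, band = c(4, 100)) {
  fs <- ts$fs
  n <- ncol(ts$data)
  if (n < fs) stop("signal shorter than one epoch (1 s)")
  ord <- min(2L * floor(n / 6), 3L * round(fs / band[1]))
  ord <- max(ord - ord %% 2L, 10L)
  b <- signal::fir1(ord, band / (fs / 2), type = "pass")
  proc <- apply(ts$data, 1, function(x) {
    x <- x - mean(x)
    x <- as.numeric(signal::filtfilt(b, x))
    s <- stats::sd(x)
    if (s == 0) x else (x - mean(x)) / s
  })
  len <- as.integer(fs)
  n_ep <- floor(n / len)
  arr <- array(NA_real_, c(n_ep, len, nrow(ts$data)),
               dimnames = list(NULL, NULL, ts$labels))
  for (e in seq_len(n_ep))
    arr[e, , ] <- proc[((e - 1) * len + 1):(e * len), , drop = FALSE]
  bad <- apply(arr, 1, function(ep) any(abs(ep) > artifact_z))
  structure(list(epochs = arr[!bad, , , drop = FALSE], labels = ts$labels,
                 fs = fs, n_dropped = sum(bad)),
            class = "cbgt_epochs")
}

# Hann-windowed segment FFTs; rows = segments
segment_ffts <- function(x, fs, seg_len) {
  if (is.matrix(x)) segs <- x else {
    n_seg <- floor(length(x) / seg_len)
    if (n_seg < 1) stop("signal shorter than one segment")
    segs <- matrix(x[seq_len(n_seg * seg_len)], n_seg, seg_len, byrow = TRUE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  t(apply(segs, 1, function(s) stats::fft(s * w)))
}

#' Welch power spectral density
#'
#' Mean of Hann-windowed periodograms over non-overlapping segments
#' (one-sided density normalization, so the spectrum integrates to the
#' signal variance). With 1 s segments at 250 Hz the resolution is 1 Hz.
#'
#' @param x numeric signal, or an epochs matrix (rows = epochs), or a
#'   [preprocess_epochs()] object (then a matrix of per-channel spectra is
#'   returned).
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples (default `fs`, i.e. 1 s).
#' @return List with `freqs` (Hz) and `psd` (vector, or channels in columns).
#' @export
welch_psd <- function(x, fs, seg_len = round(fs)) {
  if (inherits(x, "cbgt_epochs")) {
    fs <- x$fs
    ps <- vapply(seq_along(x$labels), function(k)
      welch_psd(x$epochs[, , k], fs, dim(x$epochs)[2])$psd,
      numeric(dim(x$epochs)[2] %/% 2 + 1))
    colnames(ps) <- x$labels
    return(list(freqs = seq(0, fs / 2, by = fs / dim(x$epochs)[2]), psd = ps))
  }
  F <- segment_ffts(x, fs, seg_len)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nf <- seg_len %/% 2 + 1
  scale <- 1 / (fs * sum(w^2))
  p <- colMeans(Mod(F[, seq_len(nf), drop = FALSE])^2) * scale
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  list(freqs = seq(0, fs / 2, length.out = nf), psd = p)
}

#' Remove the 1/f background from a spectrum
#'
#' Fits a line to the spectrum in log-log space over `fit_range` and
#' subtracts it (in log10 power), so a pure power-law background maps to
#' zero and spectral peaks are preserved as positive deviations.
#'
#' @param psd positive spectral values.
#' @param freqs frequency grid, Hz.
#' @param fit_range `c(low, high)` Hz over which the line is fitted
#'   (default 4-48 Hz, the analysis range of the fingerprints).
#' @return List with `freqs` (positive frequencies), `flattened` (log10
#'   residual power), `slope`, `intercept`.
#' @export
flatten_1f <- function(psd, freqs, fit_range = c(4, 48)) {
  keep <- freqs > 0
  freqs <- freqs[keep]; psd <- psd[keep]
  if (any(psd <= 0)) stop("psd must be strictly positive before log transform")
  infit <- freqs >= fit_range[1] & freqs <= fit_range[2]
  fit <- stats::lm(log10(psd[infit]) ~ log10(freqs[infit]))
  co <- stats::coef(fit)
  flattened <- log10(psd) - (co[1] + co[2] * log10(freqs))
  list(freqs = freqs, flattened = unname(flattened),
       slope = unname(co[2]), intercept = unname(co[1]))
}

# averaged auto- and cross-spectra of a channel pair
cross_spectra <- function(x, y, fs, seg_len) {
  Fx <- segment_ffts(x, fs, seg_len)
  Fy <- segment_ffts(y, fs, seg_len)
  list(fxx = colMeans(Mod(Fx)^2), fyy = colMeans(Mod(Fy)^2),
       fxy = colMeans(Fx * Conj(Fy)), n_seg = nrow(Fx), seg_len = seg_len)
}

#' Magnitude-squared coherence
#'
#' Segment-averaged `|fxy|^2 / (fxx fyy)` with Hann-windowed segments.
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples (default 1 s).
#' @return List with `freqs` and `coh` in `[0, 1]` on the one-sided grid.
#' @export
coherence_spectrum <- function(x, y, fs, seg_len = round(fs)) {
  cs <- cross_spectra(x, y, fs, seg_len)
  nf <- seg_len %/% 2 + 1
  coh <- Mod(cs$fxy)^2 / (cs$fxx * cs$fyy)
  list(freqs = seq(0, fs / 2, length.out = nf), coh = pmin(1, coh[seq_len(nf)]))
}

#' Non-parametric directionality
#'
#' Decomposes the coherence of a signal pair into forward (x leads y),
#' reverse (y leads x) and zero-lag components. Both signals are prewhitened
#' to unit autospectra (so the cross-spectrum becomes the complex coherency),
#' the coherency is transformed to the lag domain, its energy is split over
#' negative, zero and positive lags, and each part is transformed back to
#' the frequency domain. The lag-domain split is exact, so the
#' frequency-summed components add up to the frequency-summed squared
#' coherency; the per-frequency components are the squared moduli of the
#' partial coherencies.
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate, Hz.
#' @param seg_len segment length in samples (default 1 s; must allow the
#'   band resolution required).
#' @return List with `freqs`, `forward`, `reverse`, `zero_lag` (non-negative
#'   spectra on the one-sided grid) and `coherence` (prewhitened squared
#'   coherency).
#' @export
npd_spectra <- function(x, y, fs, seg_len = round(fs)) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < seg_len) stop("segment too short for the requested resolution")
  cs <- cross_spectra(x, y, fs, seg_len)
  gamma <- cs$fxy / sqrt(cs$fxx * cs$fyy)   # two-sided complex coherency
  N <- seg_len
  rho <- stats::fft(gamma, inverse = TRUE) / N   # lag-domain correlation
  half <- N %/% 2
  # with fxy = E[X conj(Y)], a copy of x delayed into y concentrates the
  # lag-domain coherency in the upper index block; the ambiguous +/- N/2 lag
  # bin is excluded from both directions so that swapping the pair mirrors
  # forward and reverse exactly
  idx_pos <- (half + 2):N             # x leads y (forward)
  idx_neg <- 2:half                   # y leads x (reverse)
  part <- function(idx) {
    r <- rep(0 + 0i, N); r[idx] <- rho[idx]
    g <- stats::fft(r)
    Mod(g)^2
  }
  fwd2 <- part(idx_pos)
  rev2 <- part(idx_neg)
  zer2 <- part(1L)
  nf <- N %/% 2 + 1
  sel <- seq_len(nf)
  # exact lag-domain energy partition (Parseval): the three parts sum to the
  # total squared coherency
  r2 <- Mod(rho)^2
  lag_split <- c(forward = sum(r2[idx_pos]), reverse = sum(r2[idx_neg]),
                 zero_lag = r2[1],
                 total = sum(r2[c(1L, idx_neg, idx_pos)]))
  list(freqs = seq(0, fs / 2, length.out = nf),
       forward = fwd2[sel], reverse = rev2[sel], zero_lag = zer2[sel],
       coherence = Mod(gamma[sel])^2, lag_split = lag_split)
}

#' Sum-of-Gaussians smoothing of a feature curve
#'
#' Fits sums of 1, 2 and 3 Gaussians to a 1-D curve on the frequency grid
#' by Levenberg-Marquardt least squares and returns the order with the best
#' adjusted R-squared. Non-converging orders fall back to the best lower
#' order with a warning.
#'
#' @param y feature values.
#' @param x frequency grid, Hz.
#' @param max_order maximum number of Gaussians (default 3).
#' @return List with `fitted` (smoothed curve), `order`, `params` (data
#'   frame amp/mu/sigma), `adj_r2`.
#' @export
gaussfit_smooth <- function(y, x, max_order = 3) {
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (stats::sd(y) < 1e-12) {
    # flat curve: degenerate single component with the curve's own level
    return(list(fitted = rep(mean(y), n), order = 1L,
                params = data.frame(amp = mean(y), mu = mean(x),
                                    sigma = diff(range(x))),
                adj_r2 = NA_real_))
  }
  fit_order <- function(k) {
    # peak-seeded starting values: split the grid and seed one Gaussian per part
    cuts <- if (k == 1) list(seq_len(n)) else
      split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
    start <- list()
    for (g in seq_len(k)) {
      idx <- cuts[[g]]
      pk <- idx[which.max(y[idx])]
      start[[paste0("a", g)]] <- max(y[pk], 1e-6)
      start[[paste0("m", g)]] <- x[pk]
      start[[paste0("s", g)]] <- diff(range(x)) / (4 * k)
    }
    terms <- paste0("a", seq_len(k), " * exp(-(x - m", seq_len(k),
                    ")^2 / (2 * s", seq_len(k), "^2))", collapse = " + ")
    form <- stats::as.formula(paste("y ~", terms))
    tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  best <- NULL; best_order <- 0L; best_r2 <- -Inf
  failed <- FALSE
  for (k in seq_len(max_order)) {
    f <- fit_order(k)
    if (is.null(f)) { failed <- TRUE; next }
    rss <- sum(stats::residuals(f)^2)
    tss <- sum((y - mean(y))^2)
    npar <- 3 * k
    adj <- 1 - (rss / max(n - npar - 1, 1)) / (tss / (n - 1))
    if (adj > best_r2) { best <- f; best_order <- k; best_r2 <- adj }
  }
  if (is.null(best)) stop("no Gaussian order converged")
  if (failed && best_order < max_order)
    warning("some orders failed to converge; using order ", best_order)
  pars <- stats::coef(best)
  params <- data.frame(
    amp = pars[paste0("a", seq_len(best_order))],
    mu = pars[paste0("m", seq_len(best_order))],
    sigma = abs(pars[paste0("s", seq_len(best_order))]))
  rownames(params) <- NULL
  list(fitted = as.numeric(stats::fitted(best)), order = best_order,
       params = params, adj_r2 = best_r2)
}

#' Summary features of a simulated run
#'
#' Computes the feature set used as a model-fitting target: per-channel
#' Welch spectra (optionally 1/f-flattened) and, for requested ordered
#' channel pairs, directional NPD spectra, all truncated to a common
#' frequency range.
#'
#' @param ts a [ts_set()] object.
#' @param pairs optional character matrix / list of 2-vectors of ordered
#'   channel pairs for NPD (default: none).
#' @param frange frequency range retained, Hz (default `c(2, 48)`).
#' @param flatten apply [flatten_1f()] to the spectra (default FALSE).
#' @param artifact_z epoch rejection threshold passed to
#'   [preprocess_epochs()].
#' @return Object of class `cbgt_features`: `freqs`, `psd` (matrix, channels
#'   in columns), `npd` (named list per "from->to" pair with forward/reverse/
#'   zero_lag), `meta`.
#' @export
feature_set <- function(ts, pairs = NULL, frange = c(2, 48), flatten = FALSE,
                        artifact_z = 6) {
  ep <- preprocess_epochs(ts, artifact_z = artifact_z)
  ps <- welch_psd(ep)
  keepf <- ps$freqs >= frange[1] & ps$freqs <= frange[2]
  psd <- ps$psd[keepf, , drop = FALSE]
  freqs <- ps$freqs[keepf]
  if (flatten) {
    psd <- vapply(seq_len(ncol(psd)), function(k) {
      fl <- flatten_1f(ps$psd[, k], ps$freqs)
      fl$flattened[fl$freqs >= frange[1] & fl$freqs <= frange[2]]
    }, numeric(sum(keepf)))
    colnames(psd) <- ts$labels
  }
  npd <- list()
  if (!is.null(pairs)) {
    if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
    for (pr in pairs) {
      d <- npd_spectra(ts_channel(ts, pr[1]), ts_channel(ts, pr[2]), ts$fs)
      sel <- d$freqs >= frange[1] & d$freqs <= frange[2]
      npd[[paste0(pr[1], "->", pr[2])]] <-
        list(forward = d$forward[sel], reverse = d$reverse[sel],
             zero_lag = d$zero_lag[sel])
    }
  }
  structure(list(freqs = freqs, psd = psd, npd = npd,
                 meta = list(fs = ts$fs, frange = frange, flatten = flatten,
                             n_epochs = dim(ep$epochs)[1])),
            class = "cbgt_features")
}
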