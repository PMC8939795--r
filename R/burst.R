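#' Band-limited analytic signal
#'
#' Applies a zero-phase fourth-order Butterworth band-pass (lower beta
#' 14-21 Hz or upper beta 21-30 Hz in the standard analyses) and returns the
#' instantaneous amplitude and phase from the Hilbert analytic signal.
#'
#' @param x numeric signal.
#' @param band `c(low, high)` in Hz.
#' @param fs sampling rate, Hz (must exceed `2 * band[2]`).
#' @param order filter order (default 4).
#' @param source optional channel label carried as provenance.
#' @return Object of class `cbgt_analytic`: list with `amp` (envelope >= 0),
#'   `phase` (radians, wrapped to (-pi, pi]), `filtered`, `band`, `fs`,
#'   `source`.
#' @export
bandpass_hilbert <- function(x, band, fs, order = 4, source = NULL) {
  if (fs < 2 * band[2]) stop("band outside Nyquist range")
  filt <- bp_filtfilt(x, band, fs, order)
  z <- analytic_signal(filt)
  structure(list(amp = Mod(z), phase = Arg(z), filtered = filt,
                 band = band, fs = fs, source = source),
            class = "cbgt_analytic")
}

#' Detect envelope bursts
#'
#' A burst is a run of samples where the envelope exceeds the given
#' percentile of the full-length envelope (linear-interpolation percentile)
#' for longer than one cycle of the band's lower cut-off frequency.
#'
#' @param env a [bandpass_hilbert()] object, or a numeric envelope (then
#'   `band` and `fs` must be given).
#' @param pct percentile threshold (default 75).
#' @param band,fs used when `env` is a plain numeric envelope.
#' @param threshold optional absolute threshold overriding the percentile
#'   (used when thresholding against a different, e.g. baseline, run).
#' @return Object of class `cbgt_bursts`: data frame `intervals` with
#'   `onset`/`offset` in seconds (disjoint, sorted, durations >= the minimum
#'   duration), plus `band`, `threshold_value`, `min_duration`, `fs`.
#' @export
detect_bursts <- function(env, pct = 75, band = NULL, fs = NULL,
                          threshold = NULL) {
  if (inherits(env, "cbgt_analytic")) {
    band <- env$band; fs <- env$fs; env <- env$amp
  }
  if (length(env) == 0L) stop("empty signal")
  stopifnot(!is.null(band), !is.null(fs))
  if (is.null(threshold)) threshold <- pct_threshold(env, pct)
  min_dur <- 1 / band[1]
  above <- env > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs >= min_dur)
  intervals <- data.frame(onset = (starts[keep] - 1L) / fs,
                          offset = ends[keep] / fs)
  structure(list(intervals = intervals, band = band,
                 threshold_value = threshold, min_duration = min_dur,
                 fs = fs),
            class = "cbgt_bursts")
}

#' @export
print.cbgt_bursts <- function(x, ...) {
  cat(sprintf("<cbgt_bursts> %d bursts, band %g-%g Hz, threshold %.4g\n",
              nrow(x$intervals), x$band[1], x$band[2], x$threshold_value))
  invisible(x)
}

# logical index of within-burst samples for a signal of n samples at fs
burst_mask <- function(bursts, n, fs) {
  m <- logical(n)
  iv <- bursts$intervals
  for (k in seq_len(nrow(iv))) {
    i0 <- floor(iv$onset[k] * fs) + 1L
    i1 <- min(n, round(iv$offset[k] * fs))
    if (i0 <= i1) m[i0:i1] <- TRUE
  }
  m
}

#' Phase locking value
#'
#' Magnitude of the mean unit phasor of a phase-difference series:
#' `|mean(exp(1i * (phi1 - phi2)))|`.
#'
#' @param phi1,phi2 phase series in radians.
#' @return Scalar in `[0, 1]`.
#' @export
plv <- function(phi1, phi2) {
  stopifnot(length(phi1) == length(phi2), length(phi1) > 0)
  Mod(mean(exp(1i * (phi1 - phi2))))
}

# phases of all channels of a ts in a band
ts_phases <- function(ts, band, order = 4) {
  vapply(ts$labels, function(lb)
    bandpass_hilbert(ts_channel(ts, lb), band, ts$fs, order)$phase,
    numeric(ncol(ts$data)))
}

#' Within-burst phase-locking matrix
#'
#' Pairwise PLV between every source pair, computed over the network-wide
#' samples falling inside the sensing-site (STN) burst windows. Phases are
#' taken from the band-limited analytic signal of each channel.
#'
#' @param ts a [ts_set()] object.
#' @param bursts a [detect_bursts()] object from the sensing channel.
#' @param band `c(low, high)` Hz for the phase extraction.
#' @return Object of class `cbgt_plvmat`: list with `values` (symmetric
#'   matrix, diagonal 1), `band`, `n_bursts`.
#' @export
within_burst_plv <- function(ts, bursts, band) {
  if (nrow(bursts$intervals) == 0L) stop("no bursts")
  ph <- ts_phases(ts, band)
  mask <- burst_mask(bursts, ncol(ts$data), ts$fs)
  if (!any(mask)) stop("zero within-burst samples")
  ph <- ph[mask, , drop = FALSE]
  z <- exp(1i * ph)
  nc <- ncol(z)
  vals <- matrix(1, nc, nc, dimnames = list(ts$labels, ts$labels))
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    vals[a, b] <- vals[b, a] <- Mod(mean(z[, a] * Conj(z[, b])))
  }
  structure(list(values = vals, band = band,
                 n_bursts = nrow(bursts$intervals)),
            class = "cbgt_plvmat")
}

# draw out-of-burst segments matched in count and duration to the bursts;
# returns a list of integer index vectors into the sample grid
draw_matched_segments <- function(bursts, n, fs) {
  mask <- burst_mask(bursts, n, fs)
  lens <- round((bursts$intervals$offset - bursts$intervals$onset) * fs)
  free <- which(!mask)
  segs <- vector("list", length(lens))
  for (k in seq_along(lens)) {
    L <- lens[k]
    # candidate starts whose whole window is out-of-burst and in range
    ok <- free[free + L - 1L <= n]
    ok <- ok[!mask[pmin(n, ok + L - 1L)]]
    if (length(ok) == 0L)
      stop(sprintf(paste0("insufficient out-of-burst data: need a segment of",
                          " %d samples, %d out-of-burst samples available"),
                   L, length(free)))
    s <- ok[sample.int(length(ok), 1L)]
    segs[[k]] <- s:(s + L - 1L)
  }
  segs
}

#' Surrogate null for within-burst PLV
#'
#' Builds the permutation null of the within-burst PLV for every channel
#' pair: out-of-burst segments matched in number and duration to the real
#' bursts are drawn at random, the segment correspondence between the two
#' channels of a pair is shuffled (segment k of channel A paired with a
#' random segment of channel B, truncated to the shorter), and the PLV of
#' the concatenated surrogate samples is computed. The per-pair significance
#' threshold is the 95th percentile of the `n_perm` surrogate PLVs. This
#' preserves the spectral content of each channel while destroying the
#' temporal correspondence between them.
#'
#' @param ts a [ts_set()] object.
#' @param bursts a [detect_bursts()] object.
#' @param band `c(low, high)` Hz.
#' @param n_perm number of permutations (default 500).
#' @param prob percentile of the null used as threshold (default 0.95).
#' @return List with `threshold` (matrix, per pair), `null` (n_perm x n_pairs
#'   matrix of surrogate PLVs), `observed` (within-burst PLV matrix).
#' @export
plv_surrogate_null <- function(ts, bursts, band, n_perm = 500, prob = 0.95) {
  n <- ncol(ts$data)
  ph <- ts_phases(ts, band)
  z <- exp(1i * ph)
  obs <- within_burst_plv(ts, bursts, band)$values
  nb <- nrow(bursts$intervals)
  nc <- ncol(z)
  pairs <- which(upper.tri(obs), arr.ind = TRUE)
  null <- matrix(NA_real_, n_perm, nrow(pairs))
  for (p in seq_len(n_perm)) {
    segs <- draw_matched_segments(bursts, n, ts$fs)
    perm <- sample.int(nb)
    for (q in seq_len(nrow(pairs))) {
      a <- pairs[q, 1]; b <- pairs[q, 2]
      acc <- 0 + 0i
      nacc <- 0L
      for (k in seq_len(nb)) {
        ia <- segs[[k]]; ib <- segs[[perm[k]]]
        L <- min(length(ia), length(ib))
        acc <- acc + sum(z[ia[seq_len(L)], a] * Conj(z[ib[seq_len(L)], b]))
        nacc <- nacc + L
      }
      null[p, q] <- Mod(acc / nacc)
    }
  }
  thr <- matrix(NA_real_, nc, nc, dimnames = dimnames(obs))
  for (q in seq_len(nrow(pairs))) {
    v <- pct_threshold(null[, q], prob * 100)
    thr[pairs[q, 1], pairs[q, 2]] <- thr[pairs[q, 2], pairs[q, 1]] <- v
  }
  list(threshold = thr, null = null, observed = obs)
}

#' Burst-onset-locked phase-difference and PLV traces
#'
#' Tracks the evolution of the phase difference between a channel pair
#' across bursts with a sliding window (200 ms, 95% overlap by default).
#' For each burst, windows are anchored at burst onset (t = 0); within each
#' window the circular mean phase difference and the temporal PLV are
#' computed, and traces are averaged across bursts (circular mean +/-
#' circular SEM for phase; mean +/- SEM for PLV). Phase traces are centred
#' so the mean phase at t = 0 is 0.
#'
#' @param ts a [ts_set()] object.
#' @param bursts a [detect_bursts()] object.
#' @param pair character vector of two channel labels, e.g. `c("M2", "STN")`.
#' @param band `c(low, high)` Hz.
#' @param win window duration, seconds (default 0.2).
#' @param overlap fractional window overlap (default 0.95).
#' @param trace_len trace duration after onset, seconds (default 0.75).
#' @param centre logical; centre the phase trace at t = 0 (default TRUE).
#' @return List with `time` (window centres relative to onset), `phase`
#'   (circular mean trace), `phase_sem`, `plv`, `plv_sem`, `n_bursts` used,
#'   `n_excluded` (bursts shorter than one window), and `per_burst` matrices.
#' @export
time_resolved_phase <- function(ts, bursts, pair = c("M2", "STN"),
                                band = c(14, 21), win = 0.2, overlap = 0.95,
                                trace_len = 0.75, centre = TRUE) {
  fs <- ts$fs
  wlen <- round(win * fs)
  hop_s <- max(1 / fs, win * (1 - overlap))
  a1 <- bandpass_hilbert(ts_channel(ts, pair[1]), band, fs)
  a2 <- bandpass_hilbert(ts_channel(ts, pair[2]), band, fs)
  theta <- phase_diff(a1$phase, a2$phase)
  zc <- exp(1i * theta)
  n <- length(theta)
  # window starts laid out on the nominal (continuous-time) hop grid, then
  # quantized to samples, so the average hop stays exact at any rate
  starts_rel <- unique(round(seq(0, trace_len - win, by = hop_s) * fs))
  tctr <- (starts_rel + wlen / 2) / fs
  iv <- bursts$intervals
  keep <- (iv$offset - iv$onset) >= win
  n_excluded <- sum(!keep)
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0L) stop("no bursts at least one window long")
  ph_mat <- matrix(NA_real_, nrow(iv), length(starts_rel))
  plv_mat <- matrix(NA_real_, nrow(iv), length(starts_rel))
  for (k in seq_len(nrow(iv))) {
    o <- floor(iv$onset[k] * fs) + 1L
    for (w in seq_along(starts_rel)) {
      i0 <- o + starts_rel[w]
      i1 <- i0 + wlen - 1L
      if (i1 > n) break
      zw <- zc[i0:i1]
      ph_mat[k, w] <- Arg(mean(zw))
      plv_mat[k, w] <- Mod(mean(zw))
    }
  }
  circ_col <- function(m) apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA, NA, 0))
    r <- mean(exp(1i * col))
    sd <- sqrt(pmax(0, -2 * log(Mod(r))))
    c(Arg(r), sd / sqrt(length(col)), length(col))
  })
  pc <- circ_col(ph_mat)
  phase <- pc[1, ]
  if (centre) phase <- wrap_phase(phase - phase[1])
  plv_mean <- colMeans(plv_mat, na.rm = TRUE)
  plv_sem <- apply(plv_mat, 2, function(c0)
    stats::sd(c0, na.rm = TRUE) / sqrt(sum(!is.na(c0))))
  list(time = tctr, phase = phase, phase_sem = pc[2, ], plv = plv_mean,
       plv_sem = plv_sem, n_bursts = nrow(iv), n_excluded = n_excluded,
       per_burst = list(phase = ph_mat, plv = plv_mat))
}

#' Relative phase stability
#'
#' Mean absolute rate of change of a wrapped phase-difference trace over a
#' time window after burst onset; 0 indicates constant phase alignment, and
#' a linear drift at `w` rad/s yields `w`. Differences are taken on the
#' circle (wrap-safe).
#'
#' @param theta phase-difference series in radians.
#' @param fs sampling rate of the series, Hz.
#' @param window `c(t0, t1)` window in seconds relative to the first sample
#'   (default `c(0, 0.5)`).
#' @return Scalar RPS in rad/s.
#' @export
relative_phase_stability <- function(theta, fs, window = c(0, 0.5)) {
  i0 <- floor(window[1] * fs) + 1L
  i1 <- round(window[2] * fs) + 1L
  if (i1 > length(theta)) stop("trace does not cover the window")
  th <- theta[i0:i1]
  dphi <- Arg(exp(1i * diff(th)))
  mean(abs(dphi)) * fs
}

#' Per-burst power versus phase stability
#'
#' For each burst: the mean squared band-limited envelope of the sensing
#' channel (burst power) and the RPS of the pair's phase difference over the
#' window after onset; returns the Pearson correlation across bursts.
#'
#' @param ts a [ts_set()] object.
#' @param bursts a [detect_bursts()] object.
#' @param pair two channel labels, phase difference is `pair[1] - pair[2]`.
#' @param sense channel whose envelope defines burst power (default "STN").
#' @param band `c(low, high)` Hz.
#' @param window RPS window after onset, seconds.
#' @return List with per-burst data frame (`power`, `rps`), `r`, `p`.
#' @export
burst_power_rps_correlation <- function(ts, bursts, pair = c("M2", "STN"),
                                        sense = "STN", band = c(14, 21),
                                        window = c(0, 0.5)) {
  iv <- bursts$intervals
  if (nrow(iv) < 3L) stop("need at least 3 bursts")
  fs <- ts$fs
  env <- bandpass_hilbert(ts_channel(ts, sense), band, fs)$amp
  a1 <- bandpass_hilbert(ts_channel(ts, pair[1]), band, fs)
  a2 <- bandpass_hilbert(ts_channel(ts, pair[2]), band, fs)
  theta <- phase_diff(a1$phase, a2$phase)
  n <- length(theta)
  res <- data.frame(power = numeric(nrow(iv)), rps = numeric(nrow(iv)))
  for (k in seq_len(nrow(iv))) {
    i0 <- floor(iv$onset[k] * fs) + 1L
    i1 <- min(n, round(iv$offset[k] * fs))
    res$power[k] <- mean(env[i0:i1]^2)
    iw <- min(n, i0 + round(diff(window) * fs))
    res$rps[k] <- relative_phase_stability(theta[i0:iw], fs,
                                           c(0, (iw - i0) / fs))
  }
  if (stats::sd(res$power) == 0 || stats::sd(res$rps) == 0)
    return(list(per_burst = res, r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(res$power, res$rps)
  list(per_burst = res, r = unname(ct$estimate), p = ct$p.value)
}
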