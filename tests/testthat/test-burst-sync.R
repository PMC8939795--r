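fs <- 250

test_that("band-limited analytic signal recovers amplitude and phase", {
  t <- seq_len(20 * fs) / fs
  a <- 1.7
  an <- bandpass_hilbert(a * sin(2 * pi * 18 * t), c(14, 21), fs)
  mid <- (2 * fs):(18 * fs)
  expect_equal(median(an$amp[mid]), a, tolerance = 0.02)
  # phase advances 2*pi per cycle
  dphi <- Arg(exp(1i * diff(an$phase[mid])))
  expect_equal(mean(dphi) * fs / (2 * pi), 18, tolerance = 0.01)

  # out-of-band tone attenuated consistently with the filter's |H|^2
  bf <- signal::butter(4, c(14, 21) / (fs / 2), type = "pass")
  h <- signal::freqz(bf, Fs = fs)
  H50 <- abs(h$h[which.min(abs(h$f - 50))])^2
  an50 <- bandpass_hilbert(sin(2 * pi * 50 * t), c(14, 21), fs)
  expect_lt(median(an50$amp[mid]), 50 * H50)
  expect_error(bandpass_hilbert(rnorm(100), c(14, 130), fs), "Nyquist")
})

test_that("burst detection applies threshold, duration and percentile rules", {
  # constructed envelope: baseline 0.1 with known suprathreshold runs
  env <- rep(0.1, 10 * fs)
  put <- function(env, at, len) {
    env[(at * fs):(at * fs + len * fs - 1)] <- 1; env
  }
  env1 <- put(env, 2, 0.100)          # 100 ms >= 1/14 s => kept
  b1 <- detect_bursts(env1, band = c(14, 21), fs = fs, threshold = 0.5)
  expect_equal(nrow(b1$intervals), 1)
  expect_equal(b1$intervals$onset, 2, tolerance = 2 / fs)

  env2 <- put(env, 2, 0.050)          # 50 ms < 71.4 ms => dropped
  b2 <- detect_bursts(env2, band = c(14, 21), fs = fs, threshold = 0.5)
  expect_equal(nrow(b2$intervals), 0)

  # linear-interpolation percentile convention
  b3 <- detect_bursts(c(1, 2, 3, 4), pct = 75, band = c(14, 21), fs = fs)
  expect_equal(b3$threshold_value, 3.25)
  expect_error(detect_bursts(numeric(0), band = c(14, 21), fs = fs), "empty")

  # monotonicity: raising the percentile never increases the burst count
  set.seed(8)
  an <- bandpass_hilbert(rnorm(60 * fs), c(14, 21), fs)
  counts <- sapply(c(50, 75, 90), function(p)
    nrow(detect_bursts(an, pct = p)$intervals))
  expect_true(all(diff(counts) <= 0))
})

test_that("PLV matches its definition and invariances", {
  set.seed(9)
  phi <- runif(500, -pi, pi)
  expect_equal(plv(phi, phi), 1)
  expect_equal(plv(phi + 1.3, phi), 1)          # constant offset
  eq <- seq(0, 2 * pi, length.out = 21)[-21]    # equally spaced phases
  expect_lt(plv(eq, numeric(20)), 1e-12)
  # null scaling: E[PLV] ~ sqrt(pi)/(2 sqrt(N)) for independent phases
  N <- 200
  m <- mean(replicate(1000, plv(runif(N, -pi, pi), runif(N, -pi, pi))))
  expect_equal(m, sqrt(pi) / (2 * sqrt(N)), tolerance = 0.05)
})

test_that("within-burst PLV and its surrogate null separate coupling", {
  # coupled pair: common oscillator with von Mises jitter
  cp <- gen_coupled_pair(fs = fs, duration = 60, plv_target = 0.9,
                         phase_lag = 0.8, seed = 10)
  an <- bandpass_hilbert(ts_channel(cp$ts, "A"), c(14, 21), fs)
  bursts <- detect_bursts(an)
  pm <- within_burst_plv(cp$ts, bursts, c(14, 21))
  expect_equal(diag(pm$values), c(A = 1, B = 1))
  expect_gt(pm$values["A", "B"], 0.8)

  sn <- plv_surrogate_null(cp$ts, bursts, c(14, 21), n_perm = 100)
  expect_gt(sn$observed["A", "B"], sn$threshold["A", "B"])

  # independent channels: observed PLV below the 95% null threshold
  set.seed(11)
  ind <- ts_set(rbind(A = rnorm(60 * fs), B = rnorm(60 * fs)),
                c("A", "B"), fs)
  anA <- bandpass_hilbert(ts_channel(ind, "A"), c(14, 21), fs)
  b2 <- detect_bursts(anA)
  sn2 <- plv_surrogate_null(ind, b2, c(14, 21), n_perm = 100)
  expect_lt(sn2$observed["A", "B"], sn2$threshold["A", "B"])
})

test_that("time-resolved phase traces track lags and transitions", {
  t <- seq_len(30 * fs) / fs
  sg <- narrowband_signal(length(t), fs, seed = 12)
  x <- sg$x
  lag <- pi / 3
  # exact constant phase shift via the analytic signal rotation
  z <- analytic_x <- exp(1i * (sg$phase))
  y <- Re(exp(-1i * lag) * z)
  ts <- ts_set(rbind(M2 = x, STN = y), c("M2", "STN"), fs)
  bursts <- structure(list(intervals = data.frame(
    onset = c(2, 6, 10, 14, 18), offset = c(2, 6, 10, 14, 18) + 1.2),
    band = c(14, 21), fs = fs), class = "cbgt_bursts")
  tr <- time_resolved_phase(ts, bursts, win = 0.2, overlap = 0.95,
                            trace_len = 0.6, centre = FALSE)
  # 200 ms / 95% overlap => 10 ms hop (exact on average; quantized to samples)
  expect_equal(mean(diff(tr$time)), 0.01, tolerance = 1e-6)
  expect_true(all(abs(diff(tr$time) - 0.01) <= 1 / fs))
  # y lags by `lag`, so the M2 - STN phase difference is +lag
  expect_equal(unname(tr$phase), rep(lag, length(tr$phase)),
               tolerance = 0.02)
  expect_true(all(tr$phase_sem < 0.02))
  expect_true(all(tr$plv > 0.99))

  # step change in lag at 0.3 s after onset transitions within one window
  y2 <- Re(exp(-1i * lag) * z)
  for (o in bursts$intervals$onset) {
    i <- round((o + 0.3) * fs):round((o + 0.7) * fs)
    y2[i] <- Re(z[i])    # lag drops to 0 between 0.3 and 0.7 s after onset
  }
  ts2 <- ts_set(rbind(M2 = x, STN = y2), c("M2", "STN"), fs)
  tr2 <- time_resolved_phase(ts2, bursts, trace_len = 0.6, centre = FALSE)
  early <- tr2$time < 0.15
  late <- tr2$time > 0.45
  expect_equal(mean(tr2$phase[early]), lag, tolerance = 0.1)
  expect_equal(mean(tr2$phase[late]), 0, tolerance = 0.1)
})

test_that("relative phase stability measures the drift rate", {
  n <- 2 * fs
  expect_equal(relative_phase_stability(rep(0.7, n), fs), 0)
  w <- 3.1
  drift <- w * seq_len(n) / fs
  expect_equal(relative_phase_stability(drift, fs), w, tolerance = 1e-9)
  # wrapping: same drift wrapped to (-pi, pi] gives the same RPS
  expect_equal(relative_phase_stability(wrap_phase(drift), fs), w,
               tolerance = 1e-9)
  # time rescaling by c scales RPS by c
  expect_equal(relative_phase_stability(drift[seq(1, n, 2)], fs / 2,
                                        window = c(0, 0.5)),
               w, tolerance = 1e-9)
  expect_error(relative_phase_stability(c(1, 2), fs), "window")
})

test_that("burst power correlates with phase stability on synthetic bursts", {
  sim <- default_run(duration = 66)
  an <- bandpass_hilbert(ts_channel(sim, "STN"), c(14, 21), sim$fs)
  bursts <- detect_bursts(an)
  res <- burst_power_rps_correlation(sim, bursts)
  expect_gte(res$r, -1); expect_lte(res$r, 1)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(nrow(res$per_burst), nrow(bursts$intervals))
  few <- bursts; few$intervals <- bursts$intervals[1:2, ]
  expect_error(burst_power_rps_correlation(sim, few), "at least 3")
})
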