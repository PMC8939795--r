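fs <- 250

test_that("von Mises sampler and concentration inversion agree", {
  expect_equal(kappa_for_plv(0), 0)
  for (p in c(0.3, 0.6, 0.9)) {
    k <- kappa_for_plv(p)
    expect_equal(besselI(k, 1, expon.scaled = TRUE) /
                   besselI(k, 0, expon.scaled = TRUE), p, tolerance = 1e-6)
  }
  set.seed(30)
  a <- rvonmises(5000, mu = 1, kappa = 3)
  r <- mean(exp(1i * a))
  expect_equal(Arg(r), 1, tolerance = 0.05)
  expect_equal(Mod(r), besselI(3, 1, TRUE) / besselI(3, 0, TRUE),
               tolerance = 0.03)
  expect_lt(Mod(mean(exp(1i * rvonmises(5000, 0, 0)))), 0.05)
})

test_that("bursty oscillation fixture ships recoverable ground truth", {
  fx <- gen_bursty_oscillation(duration = 40, snr_db = Inf, seed = 1)
  an <- bandpass_hilbert(ts_channel(fx$ts, "STN"), c(14, 21), fs)
  det <- detect_bursts(an, band = c(14, 21), fs = fs, threshold = 0.6)
  expect_equal(nrow(det$intervals), nrow(fx$truth))
  tol <- 1 / 14   # one cycle of the lower cutoff
  expect_true(all(abs(det$intervals$onset - fx$truth$onset) <= tol))
  expect_true(all(abs(det$intervals$offset - fx$truth$offset) <= tol))

  # seed-fixed repeatability
  fx2 <- gen_bursty_oscillation(duration = 40, snr_db = Inf, seed = 1)
  expect_identical(fx$ts$data, fx2$ts$data)
  expect_identical(fx$truth, fx2$truth)
})

test_that("burst-free fixtures yield only short threshold crossings", {
  # a homogeneous band-limited envelope crosses its own 75th percentile with
  # runs on the scale of the filter's correlation time, so crossings cannot
  # be eliminated: the signature of a burst-free signal is that the detected
  # run durations stay near the minimum-duration floor
  durs <- unlist(lapply(1:10, function(sd) {
    fx <- gen_bursty_oscillation(duration = 30, burst_rate = 0,
                                 snr_db = 5, seed = sd)
    an <- bandpass_hilbert(ts_channel(fx$ts, "STN"), c(14, 21), fs)
    iv <- detect_bursts(an, pct = 75)$intervals
    iv$offset - iv$onset
  }))
  min_dur <- 1 / 14
  expect_lt(median(durs), 2.5 * min_dur)
  # true bursts, by contrast, survive at their generated length
  fx <- gen_bursty_oscillation(duration = 30, burst_rate = 0.4,
                               burst_len = 0.4, snr_db = 10, seed = 1)
  an <- bandpass_hilbert(ts_channel(fx$ts, "STN"), c(14, 21), fs)
  iv <- detect_bursts(an, pct = 75)$intervals
  long <- iv[iv$offset - iv$onset > 0.25, ]
  expect_gte(nrow(long), nrow(fx$truth) * 0.7)
})

test_that("coupled pair fixture hits its PLV and lag targets", {
  cp1 <- gen_coupled_pair(duration = 40, plv_target = 1, phase_lag = pi / 3,
                          seed = 2)
  a <- bandpass_hilbert(ts_channel(cp1$ts, "A"), c(14, 21), fs)
  b <- bandpass_hilbert(ts_channel(cp1$ts, "B"), c(14, 21), fs)
  mid <- (2 * fs):(38 * fs)
  expect_gt(plv(a$phase[mid], b$phase[mid]), 0.99)
  lag <- Arg(mean(exp(1i * (a$phase[mid] - b$phase[mid]))))
  expect_equal(lag * 180 / pi, 60, tolerance = 0.05)

  cp5 <- gen_coupled_pair(duration = 40, plv_target = 0.5, seed = 3)
  expect_equal(plv(cp5$phases[, "A"], cp5$phases[, "B"]), 0.5,
               tolerance = 0.1)

  cp0 <- gen_coupled_pair(duration = 40, plv_target = 0, seed = 4)
  n <- nrow(cp0$phases)
  expect_lt(plv(cp0$phases[, "A"], cp0$phases[, "B"]), 3 / sqrt(n))
})

test_that("time series and feature CSV round-trips preserve content", {
  sim <- default_run(duration = 6)
  path <- tempfile(fileext = ".csv")
  write_ts_csv(sim, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_ts_csv(path)
  expect_equal(back$data, sim$data, tolerance = 1e-9)
  expect_equal(back$fs, sim$fs)
  expect_equal(back$labels, sim$labels)

  f <- feature_set(sim, pairs = list(c("M2", "STN")))
  fpath <- tempfile(fileext = ".csv")
  write_feature_csv(f, fpath)
  fb <- read_feature_csv(fpath)
  expect_equal(fb$freqs, f$freqs)
  expect_equal(unname(fb$psd), unname(f$psd), tolerance = 1e-9)
  expect_equal(fb$npd[["M2->STN"]]$forward, f$npd[["M2->STN"]]$forward,
               tolerance = 1e-9)
  expect_lt(feature_distance(fb, f), 1e-15)
})

test_that("synthetic ABC targets are reproducible feature sets", {
  circ <- set_pathway_weight(cbgt_circuit(), "PS", 1.2)
  tg <- gen_abc_target(circ, duration = 10, seed = 5,
                       channels = c("M2", "STN"))
  expect_s3_class(tg$features, "cbgt_features")
  expect_equal(colnames(tg$features$psd), c("M2", "STN"))
  tg2 <- gen_abc_target(circ, duration = 10, seed = 5,
                        channels = c("M2", "STN"))
  expect_equal(feature_distance(tg$features, tg2$features), 0)
})

test_that("the command line interface is reproducible and validates input", {
  out1 <- file.path(tempdir(), "fx1.csv")
  out2 <- file.path(tempdir(), "fx2.csv")
  expect_equal(cli_entry(c("fixtures", "--kind", "coupled_pair", "--seed",
                           "1", "--duration", "5", "--out", out1)), 0L)
  expect_equal(cli_entry(c("fixtures", "--kind", "coupled_pair", "--seed",
                           "1", "--duration", "5", "--out", out2)), 0L)
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))
  expect_true(file.exists(paste0(out1, ".provenance.json")))

  expect_equal(suppressMessages(
    cli_entry(c("simulate", "--config", "/nonexistent.yaml",
                "--out", tempfile()))), 1L)
  expect_equal(suppressMessages(cli_entry(c("bogus"))), 1L)
  expect_equal(suppressMessages(cli_entry(character(0))), 1L)

  simout <- file.path(tempdir(), "sim.csv")
  expect_equal(cli_entry(c("simulate", "--seed", "1", "--duration", "5",
                           "--out", simout)), 0L)
  anout <- file.path(tempdir(), "an")
  expect_equal(cli_entry(c("analyze", "--in", simout, "--what",
                           "bursts,plv", "--out", anout)), 0L)
  expect_true(file.exists(paste0(anout, "_bursts.csv")))
  expect_true(file.exists(paste0(anout, "_plv.csv")))

  stout <- file.path(tempdir(), "state.yaml")
  expect_equal(cli_entry(c("states", "--pathway", "HD", "--mode", "down",
                           "--out", stout)), 0L)
  st <- read_circuit_yaml(stout)
  k <- which(st$inter$from == "M2" & st$inter$to == "STN")
  expect_equal(st$inter$weight[k],
               0.3 * cbgt_circuit()$inter$weight[k])
})
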