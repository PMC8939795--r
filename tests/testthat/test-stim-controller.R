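fs <- 250

test_that("on-line phase tracks a pure sine at the assumed frequency", {
  cfg <- controller_config()
  t <- seq_len(3 * fs) / fs
  # 18 Hz sine with a known phase at the window end
  for (phi_end in c(0.3, pi / 2, -2, 3)) {
    x <- sin(2 * pi * 18 * (t - t[length(t)]) + phi_end)
    est <- online_phase_envelope(x, cfg, fs)
    expect_true(est$available)
    # edge ringing at the pad boundary shifts the crossing by a degree or two
    expect_lt(abs(Arg(exp(1i * (est$phase_now - phi_end)))), 10 * pi / 180)
    # causality margin: the crossing used lies before the gated read-out
    expect_lte(est$t_zc, (length(x) - 1) / fs - cfg$gating_delay)
  }
})

test_that("extrapolating a 16 Hz rhythm at 18 Hz gives the 40 degree error", {
  cfg <- controller_config()
  n <- 3 * fs
  # place the last positive zero-crossing exactly one assumed period (1/18 s)
  # before the window end: x(t) = sin(2*pi*16*(t - t_zc))
  t <- (seq_len(n) - 1) / fs
  t_zc <- t[n] - 1 / 18
  x <- sin(2 * pi * 16 * (t - t_zc))
  est <- online_phase_envelope(x, cfg, fs)
  true_phase <- 2 * pi * 16 * (1 / 18)
  err <- abs(Arg(exp(1i * (est$phase_now - true_phase)))) * 180 / pi
  expect_equal(err, 40, tolerance = 0.1)
})

test_that("flat input yields the phase-unavailable signal", {
  cfg <- controller_config()
  est <- online_phase_envelope(rep(1, 3 * fs), cfg, fs)
  expect_false(est$available)
  expect_true(is.na(est$phase_now))
})

test_that("gating applies the strict threshold and the refractory rule", {
  cfg <- controller_config()   # stim 0.5 s + refractory 0.5 s
  expect_false(gate_stim(1.0, 1.0, -Inf, 10, cfg))     # boundary: strict
  expect_true(gate_stim(1.01, 1.0, -Inf, 10, cfg))
  expect_false(gate_stim(2, 1, last_stim = 10, now = 10.4, cfg))
  expect_false(gate_stim(2, 1, last_stim = 10, now = 10.9, cfg))
  expect_true(gate_stim(2, 1, last_stim = 10, now = 11.2, cfg))
})

test_that("stimulation waveform follows the gated shifted sinusoid", {
  cfg <- controller_config(phase_shift = 0)
  expect_equal(stim_waveform(1.2, cfg, crit = FALSE, amplitude = 2), 0)
  expect_equal(stim_waveform(pi / 2, cfg, crit = TRUE, amplitude = 2), 2)
  cfg_pi <- controller_config(phase_shift = pi)
  expect_equal(stim_waveform(0.7, cfg_pi, TRUE, 2),
               -stim_waveform(0.7, cfg, TRUE, 2))
})

test_that("closed-loop phase accuracy stays within the stated worst case", {
  # frequency-wandering oscillation at 18 +/- 1 Hz
  cfg <- controller_config()
  sg <- narrowband_signal(40 * fs, fs, f0 = 18, fdev = 1, seed = 5)
  x <- sg$x
  true_phase <- sg$phase + pi / 2   # cos(phi) = sin(phi + pi/2) convention
  errs <- sapply(seq(3 * fs, length(x), by = round(0.025 * fs)), function(j) {
    est <- online_phase_envelope(x[(j - 3 * fs + 1):j], cfg, fs)
    if (!est$available) return(NA_real_)
    abs(Arg(exp(1i * (est$phase_now - true_phase[j])))) * 180 / pi
  })
  expect_lt(median(errs, na.rm = TRUE), 40)
})

test_that("a zero-amplitude sweep reproduces the baseline bit for bit", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 8, seed = 3)
  ctl <- controller_config(amplitude_ratio = 0)
  sw <- run_phase_sweep(circ, cfg, ctl, phases_deg = seq(-180, 150, by = 30))
  expect_length(sw$runs, 12)
  expect_equal(diff(sw$phases_deg), rep(30, 11))
  for (r in sw$runs) expect_identical(r$data, sw$baseline$data)
  arc <- amplitude_response_curves(sw)
  expect_true(all(abs(arc$arc$pct_change) < 1e-9, na.rm = TRUE))
})

test_that("gate-closed and playback-of-silence runs equal the baseline", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 8, seed = 4)
  baseline <- simulate_cbgt(circ, cfg)
  ctl <- controller_config(threshold = Inf)
  stim <- simulate_stimulation(circ, cfg, ctl)
  expect_identical(stim$data, baseline$data)
  expect_length(stim$stim_record$stim_onsets, 0)

  fixed <- control_policies(circ, cfg, controller_config(threshold = Inf),
                            mode = "fixed_freq")
  expect_identical(fixed$data, baseline$data)

  silent_rec <- list(waveform = numeric(1000), stim_onsets = numeric(0))
  pb <- control_policies(circ, cfg, controller_config(), mode = "playback",
                         playback_record = silent_rec)
  expect_identical(pb$data, baseline$data)
})

test_that("stimulated runs are reproducible and respect the refractory period", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 24, seed = 1)
  ctl <- controller_config()
  a <- simulate_stimulation(circ, cfg, ctl)
  b <- simulate_stimulation(circ, cfg, ctl)
  expect_identical(a$data, b$data)
  expect_identical(a$stim_record$stim_onsets, b$stim_record$stim_onsets)
  on <- a$stim_record$stim_onsets
  expect_gt(length(on), 1)
  expect_true(all(diff(on) >= ctl$stim_duration + ctl$refractory - 1e-9))
  # the waveform is bounded by the configured amplitude and zero between epochs
  expect_lte(max(abs(a$stim_record$waveform)), a$stim_record$amplitude + 1e-12)
  ep <- stim_epochs(a$stim_record)
  tgrid <- (seq_along(a$stim_record$waveform)) * cfg$dt
  inside <- Reduce(`|`, lapply(seq_len(nrow(ep)), function(k)
    tgrid > ep$onset[k] & tgrid <= ep$offset[k]))
  expect_true(all(a$stim_record$waveform[!inside] == 0))
})

test_that("fixed-frequency stimulation injects an exact 18 Hz sinusoid", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 24, seed = 1)
  ctl <- controller_config(mode = "fixed_freq", fixed_phase0 = 0.4)
  run <- simulate_stimulation(circ, cfg, ctl)
  w <- run$stim_record$waveform
  A <- run$stim_record$amplitude
  idx <- which(w != 0)
  expect_gt(length(idx), 100)
  tgrid <- idx * cfg$dt
  expect_equal(w[idx], A * sin(2 * pi * 18 * tgrid + 0.4), tolerance = 1e-9)
})

test_that("playback truncates an over-long record with a warning", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 6, seed = 2)
  rec <- list(waveform = numeric(round(10 / cfg$dt)), stim_onsets = numeric(0))
  expect_warning(control_policies(circ, cfg, controller_config(),
                                  mode = "playback", playback_record = rec),
                 "truncated")
})

test_that("ARC epochs are duration-matched between stim and baseline", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 24, seed = 1)
  sw <- run_phase_sweep(circ, cfg, controller_config(), phases_deg = c(0))
  run <- sw$runs[["0"]]
  ep <- stim_epochs(run$stim_record)
  expect_true(all(abs((ep$offset - ep$onset) - 0.5) < 1e-9))
  arc <- amplitude_response_curves(sw)
  expect_equal(nrow(arc$arc), 4)          # 1 phase x 2 signals x 2 bands
  expect_true(all(is.finite(arc$arc$pct_change)))
})

test_that("controller configuration invariants are enforced", {
  expect_error(controller_config(update_interval = 1), "update_interval")
  expect_error(controller_config(history_window = 0.1), "history_window")
  expect_error(controller_config(threshold_percentile = 100), "percentile")
})
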