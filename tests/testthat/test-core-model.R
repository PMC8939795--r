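test_that("sigmoid rate matches closed-form values and saturates", {
  expect_equal(sigmoid_rate(0, 3), 0.5)
  expect_equal(sigmoid_rate(0, 0.1), 0.5)
  expect_equal(sigmoid_rate(1, 2), 0.880797, tolerance = 1e-6)
  expect_equal(sigmoid_rate(1e3, 1), 1)
  expect_equal(sigmoid_rate(-1e3, 1), 0)
  v <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(sigmoid_rate(v, 2)) > 0))
  expect_error(sigmoid_rate(Inf, 1), "non-finite")
  expect_error(sigmoid_rate(0, -1), "slope")
})

test_that("afferent drive sums delayed sigmoid-coupled inputs", {
  dt <- 5e-4
  circ <- silent_circuit()
  hist0 <- matrix(0, 200, 9)
  expect_equal(afferent_drive(circ, hist0, 200 * dt, "STR", dt), 0)

  # single connection M2 -> STR, weight 2, delayed source voltage 0 => S = 0.5
  circ$inter$weight[circ$inter$from == "M2" & circ$inter$to == "STR"] <- 2
  expect_equal(afferent_drive(circ, hist0, 200 * dt, "STR", dt), 1.0)

  # known delayed voltage: delay 8 ms = 16 steps; set M2.DP voltage there
  hist1 <- hist0
  hist1[200 - 16, 3] <- 1   # M2.DP is population 3
  slope <- circ$populations$slope[3]
  expect_equal(afferent_drive(circ, hist1, 200 * dt, "STR", dt),
               2 * sigmoid_rate(1, slope))

  # delay-consistency: shifting history and delay together leaves drive fixed
  shift <- 10L
  circ2 <- circ
  circ2$inter$delay[circ2$inter$from == "M2"] <-
    circ$inter$delay[circ$inter$from == "M2"] + shift * dt
  hist2 <- rbind(hist1, matrix(0, shift, 9))
  expect_equal(afferent_drive(circ2, hist2, (200 + shift) * dt, "STR", dt),
               afferent_drive(circ, hist1, 200 * dt, "STR", dt))

  expect_error(afferent_drive(circ, hist0[1:10, ], 10 * dt, "STR", dt),
               "history shorter")
})

test_that("afferent drive sign flips exactly with the source sign", {
  dt <- 5e-4
  circ <- silent_circuit()
  circ$inter$weight[circ$inter$from == "GPe" & circ$inter$to == "STN"] <- 3
  hist1 <- matrix(0.4, 100, 9)
  d1 <- afferent_drive(circ, hist1, 100 * dt, "STN", dt)
  circ2 <- circ
  circ2$populations$sign[circ2$populations$id == "GPe"] <- "excitatory"
  d2 <- afferent_drive(circ2, hist1, 100 * dt, "STN", dt)
  expect_equal(d1, -d2)
  expect_lt(d1, 0)
})

test_that("neural mass step has the analytic fixed point", {
  circ <- cbgt_circuit()
  z <- list(v = numeric(9), vdot = numeric(9))
  s <- neural_mass_step(z, numeric(9), numeric(9), 5e-4, circ)
  expect_equal(s$v, numeric(9))
  expect_equal(s$vdot, numeric(9))

  # constant drive p0: steady state v* = H * tau * p0
  p0 <- rep(0.3, 9)
  st <- z
  for (k in 1:20000) st <- neural_mass_step(st, p0, numeric(9), 5e-4, circ)
  expect_equal(st$v, circ$populations$gain * circ$populations$tau * p0,
               tolerance = 1e-6)
  expect_error(neural_mass_step(z, rep(NA_real_, 9), numeric(9), 5e-4, circ),
               "non-finite")
})

test_that("compiled integrator matches the pure-R reference step for step", {
  circ <- cbgt_circuit()
  cfg <- sim_config(duration = 2.5, burn_in = 0.1, seed = 7)
  sim <- simulate_cbgt(circ, cfg)

  # independent R reference: same Euler-Maruyama recursion, written directly
  # from the population-level matrices
  m <- circuit_matrices(circ)
  dt <- cfg$dt
  dsteps <- matrix(0L, 9, 9)
  dsteps[m$W != 0] <- pmax(1L, as.integer(round(m$D[m$W != 0] / dt)))
  n <- round(cfg$duration / dt)
  set.seed(cfg$seed)
  noise <- matrix(rnorm(n * 9), n, 9)
  p <- circ$populations
  vbuf <- matrix(0, n, 9)
  v <- vd <- numeric(9)
  for (s in seq_len(n)) {
    drive <- numeric(9)
    for (i in 1:9) for (j in 1:9) if (m$W[i, j] != 0) {
      lag <- s - 1L - dsteps[i, j]   # state at step start is row s-1
      vdel <- if (lag >= 1) vbuf[lag, j] else 0
      drive[i] <- drive[i] + m$W[i, j] * sigmoid_rate(vdel, p$slope[j])
    }
    st <- neural_mass_step(list(v = v, vdot = vd), drive,
                           p$noise_sd * noise[s, ], dt, circ)
    v <- st$v; vd <- st$vdot
    vbuf[s, ] <- v
  }
  obs <- match(circ$observation_map, p$id)
  # compare the raw STN trajectory through the same decimation path
  b <- signal::fir1(64, 0.8 * cfg$out_rate / (1 / dt))
  ref <- as.numeric(signal::filtfilt(b, vbuf[, obs[4]]))
  keep <- seq.int(round(cfg$burn_in / dt) + 8, n, by = 8)
  expect_equal(as.numeric(sim$data["STN", ]), ref[keep], tolerance = 1e-10)
})

test_that("simulation is deterministic and silent circuits stay at rest", {
  cfg <- sim_config(duration = 4, seed = 42)
  a <- simulate_cbgt(cbgt_circuit(), cfg)
  b <- simulate_cbgt(cbgt_circuit(), cfg)
  expect_identical(a$data, b$data)

  z <- simulate_cbgt(silent_circuit(), cfg)
  expect_true(all(z$data == 0))
})

test_that("diverging trajectories raise a diagnostic naming the population", {
  circ <- cbgt_circuit()
  # Euler instability: time constant far below the step size
  circ$populations$tau[circ$populations$id == "GPe"] <- 1e-4
  expect_error(simulate_cbgt(circ, sim_config(duration = 4, seed = 1)),
               "unstable trajectory.*GPe")
})

test_that("cross-correlation lag of a delayed connection equals the delay", {
  circ <- single_pop_circuit("STN")
  k <- which(circ$inter$from == "STN" & circ$inter$to == "GPe")
  circ$inter$weight[k] <- 30
  circ$inter$delay[k] <- 0.040
  # make the target population fast so its own lag is below one output sample
  circ$populations$tau[circ$populations$id == "GPe"] <- 0.001
  sim <- simulate_cbgt(circ, sim_config(duration = 34, seed = 2))
  x <- ts_channel(sim, "STN"); y <- ts_channel(sim, "GPe")
  cc <- stats::ccf(y, x, lag.max = 30, plot = FALSE)
  lag_s <- cc$lag[which.max(abs(cc$acf))] / sim$fs
  expect_equal(lag_s, 0.040, tolerance = 1 / sim$fs + 1e-9)
})

test_that("output variance scales linearly with noise variance", {
  # an uncoupled population is linear in its noise, so variance must scale
  # with the squared noise amplitude; averaged over 20 seeds the regression
  # of variance on noise variance is proportional
  vars <- sapply(c(0.5, 1, 2), function(sc) {
    circ <- single_pop_circuit("STN")
    circ$populations$noise_scale[circ$populations$id == "STN"] <- sc
    mean(sapply(1:20, function(sd)
      var(ts_channel(simulate_cbgt(circ,
        sim_config(duration = 6, seed = sd)), "STN"))))
  })
  s2 <- c(0.5, 1, 2)^2
  slope <- sum(vars * s2) / sum(s2^2)   # least squares through the origin
  expect_equal(vars / (slope * s2), rep(1, 3), tolerance = 0.1)
  expect_equal(vars[3] / vars[1], 16, tolerance = 1e-6)
})

test_that("halving the step size changes beta band power by < 5%", {
  # the same Brownian path is integrated at dt and dt/2; near the resonance
  # the Euler scheme carries an O(dt) gain bias, so convergence is checked
  # in the converged regime (dt = 0.25 ms vs 0.125 ms)
  circ <- cbgt_circuit()
  dt <- 2.5e-4
  n_fine <- round(30 / (dt / 2))
  set.seed(11)
  fine <- matrix(rnorm(n_fine * 9), n_fine, 9)
  coarse <- (fine[seq(1, n_fine, by = 2), ] +
               fine[seq(2, n_fine, by = 2), ]) / sqrt(2)
  bpow <- function(dt, noise) {
    sim <- simulate_cbgt(circ, sim_config(duration = 30, dt = dt, seed = 11),
                         noise = noise)
    ps <- welch_psd(ts_channel(sim, "STN"), sim$fs)
    sum(ps$psd[ps$freqs >= 14 & ps$freqs <= 30])
  }
  p1 <- bpow(dt, coarse)
  p2 <- bpow(dt / 2, fine)
  expect_lt(abs(p2 - p1) / p1, 0.05)
})

test_that("default model expresses a dominant beta peak at the STN", {
  sim <- default_run()
  ps <- welch_psd(ts_channel(sim, "STN"), sim$fs)
  sel <- ps$freqs >= 2 & ps$freqs <= 100
  pk <- ps$freqs[sel][which.max(ps$psd[sel])]
  expect_gte(pk, 14)
  expect_lte(pk, 30)
})

test_that("circuit validation enforces the structural invariants", {
  circ <- cbgt_circuit()
  expect_silent(validate_circuit(circ))
  bad <- circ; bad$populations$tau[3] <- -1
  expect_error(validate_circuit(bad), "tau")
  bad <- circ; bad$populations$noise_sd[circ$populations$id == "M2.SP"] <- 1
  expect_error(validate_circuit(bad), "noise")
  bad <- circ
  bad$inter$from[1] <- "GPe"; bad$inter$to[1] <- "STR"  # not in the pattern
  expect_error(validate_circuit(bad), "sparsity")
  bad <- circ; bad$inter$delay[2] <- 0
  expect_error(validate_circuit(bad), "delay")
  expect_error(sim_config(duration = 1, burn_in = 2), "exceed")
  expect_error(sim_config(duration = 10, out_rate = 251), "divide")
})

test_that("pathway scaling and YAML serialization round-trip", {
  circ <- cbgt_circuit()
  up <- set_pathway_weight(circ, "PS", 2)
  k <- which(circ$inter$from == "GPe" & circ$inter$to == "STN")
  expect_equal(up$inter$weight[k], 2 * circ$inter$weight[k])
  expect_error(set_pathway_weight(circ, "PS", -1), "multiplier")

  path <- tempfile(fileext = ".yaml")
  write_circuit_yaml(up, path)
  back <- read_circuit_yaml(path)
  expect_equal(back$populations, up$populations)
  expect_equal(back$inter, up$inter)
  expect_equal(back$intra, up$intra)
})
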