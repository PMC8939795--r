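# shared helpers for the test suite

# circuit with every inter-source weight removed (valid variant: connections
# may be deleted, never added) and intrinsic noise silenced via noise_scale
silent_circuit <- function() {
  circ <- cbgt_circuit()
  circ$inter$weight[] <- 0
  circ$intra$weight[] <- 0
  circ$populations$noise_scale[] <- 0
  circ
}

# circuit driven by a single noisy population with all coupling removed
single_pop_circuit <- function(pop = "STN") {
  circ <- silent_circuit()
  circ$populations$noise_scale[circ$populations$id == pop] <- 1
  circ
}

# narrowband test signal with exactly known analytic phase:
# x = cos(phi), built from a wandering-frequency phase ramp inside `band`
narrowband_signal <- function(n, fs, f0 = 18, fdev = 1, seed = 1) {
  set.seed(seed)
  dev <- stats::filter(rnorm(n), rep(1 / 100, 100), circular = TRUE)
  dev <- as.numeric(dev) / stats::sd(dev) * fdev
  phi <- cumsum(2 * pi * (f0 + dev) / fs)
  list(x = cos(phi), phase = phi, freq = f0 + dev)
}

# one cached default-model run shared across test files (lazily built)
.cache <- new.env(parent = emptyenv())
default_run <- function(duration = 34, seed = 1) {
  key <- paste0("run_", duration, "_", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- simulate_cbgt(cbgt_circuit(),
                                   sim_config(duration = duration,
                                              seed = seed))
  .cache[[key]]
}
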