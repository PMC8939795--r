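Package: cbgtstim
Title: Closed-Loop Phase-Locked Stimulation in a Neural Mass Model of the
    Cortico-Basal Ganglia-Thalamic Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a stochastic delay neural mass model of the
    cortico-basal ganglia-thalamic motor circuit (motor cortex microcircuit,
    striatum, pallidal segments, subthalamic nucleus and thalamus) and an
    on-line, phase-locked cortical stimulation controller gated by
    subthalamic beta bursts. Provides the accompanying analysis stack:
    beta-burst detection, within-burst phase-locking with surrogate nulls,
    Welch spectra with 1/f flattening, non-parametric directionality,
    circular statistics and cluster-based permutation tests, spectral
    fingerprints with pooled R-squared state recovery, and a sequential
    approximate Bayesian computation fitter for circuit parameters.
    All analyses are exercised on synthetic fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
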