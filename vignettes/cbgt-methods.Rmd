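---
title: "Methods: the CBGT circuit model, closed-loop stimulation, and the analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CBGT circuit model, closed-loop stimulation, and the analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes: the circuit
model and its assumptions, the closed-loop controller, the analysis
definitions, the calibration of network states, the fitting machinery, and
the numerical choices that a user extending the package should know about.

## The circuit model

The model describes six sources of the cortico-basal ganglia-thalamic motor
circuit: secondary motor cortex (M2), striatum (STR), the external and
internal pallidal segments (GPe, GPi), the subthalamic nucleus (STN) and
ventrolateral thalamus (Thal). M2 is itself a microcircuit of four
populations — superficial (SP), middle (MP) and deep (DP) pyramidal layers
plus inhibitory interneurons (II) — so the full model has nine populations.

Each population is a neural mass: its average membrane voltage obeys the
damped second-order dynamics

$$\ddot v = \frac{H}{\tau}\,p \;-\; \frac{2}{\tau}\,\dot v \;-\;
  \frac{v}{\tau^2},$$

where `H` (mV) is the synaptic gain, `tau` (s) the lumped
membrane/synaptic time constant, and `p` the total input. A population's
output firing rate is a sigmoid of its voltage,
$S(v) = 1/(1+e^{-Rv})$, with slope `R` modelling the spread of firing
thresholds across the population. Inputs from source *m* to source *n*
arrive with connection weight $\omega_{n,m}$ (negative for inhibitory
senders, including the per-layer self-inhibition of the cortical
microcircuit) and axonal delay $D_{n,m} > 0$:

$$p_n(t) = \sum_m \omega_{n,m}\, S_m\!\big(V_m(t - D_{n,m})\big)
         + C\,u(t) + u_{\mathrm{stim}}(t).$$

The sigmoid slope used for each term is the presynaptic population's. The
stochastic input $u$ (white noise with standard deviation `noise_sd`,
scaled by `noise_scale`) drives the five subcortical populations and the
middle pyramidal layer; the other cortical layers are noiseless. The 18
first-order equations are integrated with the Euler–Maruyama scheme (the
stochastic increment scales as $\sqrt{dt}$) in a compiled core; a pure-R
step function with the identical update is part of the public API and
serves as the reference implementation in the tests.

The inter-source wiring is the standard motor loop: hyperdirect cortex→STN,
cortico-striatal input, striato-pallidal inhibition of GPe and GPi, the
reciprocal STN↔GPe pair, subthalamo-pallidal excitation of GPi,
pallido-thalamic inhibition and thalamo-cortical feedback. Within M2,
thalamic input arrives at MP, MP drives SP, SP drives DP and the
interneurons, the interneurons inhibit SP, each pyramidal layer inhibits
itself, and DP is the output layer projecting subcortically. M2 is
*observed* at the superficial layer (a surface-electrode proxy); the
subcortical sources are observed at their single population.

### The shipped default parameterization

The archived posterior of the original fitting study is not distributed
with the package, so the default circuit is a documented, seed-pinned
surrogate, designed and checked directly against the behaviours the
analyses need:

* the reciprocal STN/GPe loop is tuned near criticality so that its delayed
  negative feedback resonates at ~17–18 Hz. With loop delays of 4 ms each
  way and time constants of 5 ms (STN) and 6 ms (GPe), the half-period
  condition lands in low beta; the weight product sets the resonance gain
  just below instability, so the rhythm is noise-driven and *bursty*
  (envelope CV ≈ 0.5, ~1.5 bursts/s of median duration ~150 ms at the 75th
  percentile threshold) rather than a deterministic limit cycle;
* the cortex is the dominant stochastic driver: the middle pyramidal layer
  carries the largest intrinsic noise (`noise_sd = 1.5` against 0.05–0.1
  subcortically), and the hyperdirect projection is strong. This choice
  makes cortical input — and therefore cortical stimulation, whose
  amplitude is defined relative to that same noise — an effective modulator
  of STN beta, and it reproduces pronounced cortico-subthalamic beta
  coherence;
* the pallido-subthalamic weight acts as a broadband beta gain (its
  Up-state doubling calibrates at a multiplier of ~1.1) and hyperdirect
  down-regulation *increases* beta (the STN/GPe resonator is released),
  matching the direction of the Parkinsonian arguments the model
  represents.

The default produces a dominant STN spectral peak inside 14–30 Hz, verified
by a Welch analysis in the test suite. What the surrogate does **not**
reproduce is the bimodal β₁/β₂ spectral structure of the original fitted
model: the second, upper-beta sub-peak depended on the archived posterior.
All β₂ analyses remain available (band arguments everywhere), but on the
default circuit upper beta is a shoulder of the single resonance.

### Numerical choices

* `dt = 0.5 ms`, burn-in 2 s, outputs decimated to 250 Hz through a
  zero-phase FIR low-pass (order scaled to the decimation factor) followed
  by subsampling. Delays are rounded to integration steps, minimum one
  step, so the drive always reads strictly past states.
* Near a lightly damped resonance the Euler drift carries an $O(dt)$
  damping bias: band power at `dt = 0.5 ms` is systematically lower than
  the converged value, and the first step-halving moves it substantially.
  The scheme converges — the suite verifies that halving from 0.25 ms to
  0.125 ms changes STN beta power by ~2% on a shared Brownian path — and
  all shipped analyses are run at the same fixed `dt`, so comparisons
  between conditions are internally consistent; the tuned defaults absorb
  the bias. Users wanting bias-free absolute powers should simulate at
  `dt <= 0.25 ms`.
* Sigmoid-bounded drives make the dynamics globally bounded; the guard
  (`|v| > 1e5`) therefore only triggers on numerically unstable
  configurations (e.g. `tau` comparable to `dt`) and names the diverging
  population.
* All randomness is drawn up-front from the run seed, which is what allows
  a stimulated run to be re-simulated on the *identical* noise realization
  as its baseline — the foundation of every within-noise comparison in the
  package (a gate that never opens reproduces the baseline bit for bit).

## The closed-loop controller

The controller senses the STN at 250 Hz (the raw integration grid
subsampled; an on-line system cannot apply the zero-phase anti-alias filter
used for the offline outputs, and the beta band is far below the output
Nyquist). Every 25 ms it:

1. takes the past 3 s of sense samples, subtracts their mean, zero-pads 1 s
   on each side and applies a zero-phase 4th-order Butterworth band-pass
   (default 14–21 Hz);
2. reads the analytic envelope 25 ms before the window end (the gating
   delay protects against end-of-window edge effects of the padding);
3. finds the most recent positive-going zero-crossing before that same
   causality margin and extrapolates phase from it at the assumed 18 Hz
   (the passband centre). With the instantaneous frequency within ±2 Hz of
   the assumption, the worst-case extrapolation error over one assumed
   period is ±40°, which the tests reproduce both analytically and on a
   16 Hz rhythm. If no crossing exists (e.g. flat input) the update reports
   phase-unavailable and no new stimulation starts;
4. gates stimulation: the envelope must strictly exceed the 75th percentile
   of the *baseline* run's envelope (same band and filter), and at least
   1.0 s (500 ms stimulation + 500 ms refractory) must have passed since
   the previous onset;
5. during an epoch, injects $u = A \sin(\varphi_{sense} + \Delta\varphi)$
   into the superficial pyramidal layer's input, re-anchoring the sinusoid
   to the newest phase estimate at every update.

The amplitude is `amplitude_ratio` (default 1/4, configurable — 1/3 is the
other convention in circulation) times the intrinsic noise standard
deviation of a reference population. The stimulated layer itself carries no
intrinsic noise in this model, so the reference defaults to the cortical
noise source (M2.MP); the reference is configurable.

Control policies: `fixed_freq` keeps the same gating but injects a
free-running 18 Hz sinusoid (no phase tracking); `playback` re-injects a
recorded stimulation waveform into a run with a different noise
realization, which dissociates the waveform statistics from its phase
alignment.

The phase sweep runs 12 target phase shifts at 30° spacing against one
shared baseline (same noise, same threshold). Amplitude response curves
(ARCs) compare band power within stimulation epochs against the *identical
time windows* of the baseline run — the strongest form of duration
matching, since noise realizations agree sample for sample. On the shipped
default the β₁ ARC has both amplifying and suppressing phases with extrema
approximately 180° apart, which is the qualitative closed-loop signature
the acceptance suite checks; the printed effect magnitudes of the original
study depended on its archived posterior parameters and are out of scope.

## Burst and synchronization analyses

*Bursts* are suprathreshold runs of the band-limited analytic envelope
(zero-phase 4th-order Butterworth, Hilbert magnitude) lasting at least one
cycle of the band's lower cutoff (71.4 ms for β₁), with the threshold the
linear-interpolation percentile (default 75th) of the full envelope of the
run under analysis — thresholds are state-specific by construction.

*Within-burst PLV* concatenates all network samples inside the STN burst
windows and computes $|\,\mathrm{mean}\,e^{i(\varphi_1-\varphi_2)}|$ per
source pair. Its surrogate null redraws out-of-burst segments matched in
number and duration, shuffles the segment correspondence between the two
channels (truncating pairs to the shorter segment), and thresholds at the
95th percentile of 500 (configurable) surrogate PLVs — preserving spectral
content while destroying temporal correspondence.

*Time-resolved* traces use 200 ms windows at 95% overlap (10 ms nominal
hop, quantized to samples with the exact average hop), time-locked to burst
onset, averaged circularly across bursts, optionally centred at the onset
phase. *Relative phase stability* is the mean absolute wrapped
finite-difference rate of the phase difference (φ_M2 − φ_STN; zero for
constant alignment, `w` for a linear drift at `w` rad/s) over a window
after onset. Two windows appear in the source literature (0–500 and
0–750 ms); the default is 0–500 ms and the window is an argument.

## Circular statistics and cluster tests

Circular mean/SD use the resultant vector (SD $=\sqrt{-2\ln\bar R}$);
the Rayleigh test uses $z = n\bar R^2$ with the standard series
approximation for p; the Watson–Williams test applies the usual
concentration correction $1 + 3/(8\hat\kappa)$ and warns below pooled
$\bar R = 0.45$. The cluster permutation test forms clusters from pointwise
two-sample t-values exceeding the two-sided α threshold, uses summed-t
cluster mass against a label-permutation maximum-mass null, drops clusters
shorter than 20 ms, and reports at most the five largest. The duration
exclusion is applied inside the permutation null as well, which keeps the
reported p-values calibrated under the exclusion rule; on traces with the
smoothness this test actually sees (sliding-window outputs), the null
rejection rate sits at the nominal 5%, which the acceptance suite verifies.
On unsmoothed white-noise traces the duration rule makes the test
conservative — a property of the rule, not a defect of the implementation.

## Network states, fingerprints, pooled R²

Down-regulated states fix the pathway weight at 30% of the fitted value
(one description in the source literature says 10%; 30% is the default and
the fraction is an argument). Up-regulated states are calibrated by
bisection on the weight multiplier until STN broadband beta (14–30 Hz)
Welch power reaches 2.0× the unmodulated model's, within a 5% stopping
tolerance, averaging three fixed-seed 60 s simulations per evaluation; the
calibration record (achieved ratio, seeds, durations) travels with the
state. Bisection assumes the power ratio is monotone in the multiplier
over the bracket, which holds on the default circuit (the PS weight is the
loop gain).

A *fingerprint* summarizes activity inside a set of windows (bursts for
spontaneous runs, stimulation epochs for stimulated runs): per-source Welch
spectra of the concatenated within-window samples, truncated to 2–48 Hz and
normalized to unit variance per source, plus the β₁ and β₂ within-window
PLV matrices. Masks can exclude sources from the spectral block and
restrict the PLV block (e.g. basal-ganglia-only) for comparisons against
empirical feature sets that lack some regions.

Fingerprints are compared with a pooled R²,

$$R^2 = 1 - \frac{1}{N_f}\sum_{n=1}^{N_f}
  \frac{\sum_i (y^{state}_{n,i} - y^{stim}_{n,i})^2}
       {\sum_i (y^{stim}_{n,i} - \bar y^{stim}_{n})^2},$$

with $N_f$ the number of feature blocks used (spectra, PLV, or both); the
denominator is the stimulated features' own variance, so values below zero
mean a fit worse than the stimulated mean. `recovery_sweep` scores every
phase of a sweep against every state fingerprint with all three feature
sets, optionally realigning phases to the maximum-recovery phase;
`strength_phase_heatmap` repeats this across a pathway-strength grid from
the Down fraction to the calibrated Up multiplier.

## Sequential ABC

`sequential_abc` fits simulator parameters to target features by iterated
simulation: draw from the prior (log-normal, sd 0.5 log-units around the
shipped values for gains/weights/time constants; uniform 1–10 ms for
delays), measure the mean squared error over concatenated spectra and NPD
components, pool each generation's draws with the previous survivors, keep
the best 30% (the adaptive threshold), and resample-perturb with a Gaussian
kernel at half the survivors' spread (log-space for log-normal parameters).
Iteration stops when the relative threshold improvement drops below
`grad_tol` or at `max_gens`. The MAP estimate is the mode of each marginal
posterior. `model_evidence` estimates the marginal probability as the
fraction of posterior re-simulations landing within a common distance
threshold — the criterion for architecture comparison.

The shipped defaults (200 particles, ≤10 generations, tens-of-seconds
simulations) are desk-scale: the recovery harness in the acceptance suite
fits the two subthalamic pathway weights (truth displaced ×2 and ×0.5 from
the prior centres) in 18 s simulations and recovers both within the prior's
interquartile band. This validates the machinery, not the original study's
full inversion, which used far more computation and empirical targets.
Whether 1/f flattening is applied before the distance is a `feature_set`
argument; the default treats simulated and target features identically,
since an asymmetric transform would bias the distance.

## Synthetic fixtures: what they do and do not emulate

`gen_bursty_oscillation` produces an amplitude-modulated in-band sinusoid
(boxcar bursts, 50 ms smoothing) over a 1/f background at a chosen SNR,
returning the generating burst intervals; `gen_coupled_pair` produces a
frequency-wandering common oscillation with a fixed phase lag and i.i.d.
von Mises phase jitter whose concentration solves
$I_1(\kappa)/I_0(\kappa) = \mathrm{PLV}$, returning the ground-truth
phases; `gen_abc_target` simulates the circuit at known parameters. These
fixtures pin down estimator correctness (burst recovery, PLV bias floors at
$\sqrt{\pi}/(2\sqrt N)$, lag recovery) but are deliberately simple: they
contain no cross-frequency structure, no non-sinusoidal waveform shape, no
nonstationary noise floors, and no volume conduction. Passing tests on them
demonstrates that the estimators measure what they claim on signals with
known truth — not that the estimators are robust to every pathology of
empirical electrophysiology.

One physical point the fixtures make explicit: any band-limited envelope
crosses its own 75th percentile in runs on the scale of the filter's
correlation time (~140 ms for β₁ at 250 Hz), so threshold crossings exist
even in burst-free signals; what distinguishes true bursts is that detected
durations far exceed the one-cycle minimum.

## Known limitations

* The default circuit is a surrogate, not the archived fit: absolute effect
  sizes (ARC percentages, state-recovery R² values) are specific to this
  parameterization.
* Neural mass dynamics cannot represent spiking, conductance effects, or
  the direct biophysics of high-frequency stimulation; the lumped synaptic
  filtering suppresses drive far above the beta band.
* Stimulation is a current injection into one population — no spatial
  spread, layer specificity beyond the microcircuit, or electric-field
  modelling.
* The zero-crossing phase tracker assumes a dominant sinusoid near 18 Hz;
  its accuracy degrades with SNR and frequency deviation (the ±40° bound is
  for ±2 Hz).
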