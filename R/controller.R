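#' Closed-loop stimulation controller configuration
#'
#' Parameters of the on-line, phase-locked stimulation policy: the STN
#' band-limited envelope gates stimulation, a zero-crossing analysis tracks
#' its phase, and a sinusoidal voltage at a fixed phase shift is injected
#' into the superficial pyramidal layer of motor cortex.
#'
#' @param sense_source sensed channel (default `"STN"`).
#' @param stim_population stimulated population (default `"M2.SP"`).
#' @param band sensing band in Hz (default lower beta, 14-21 Hz).
#' @param filter_order Butterworth order for the on-line filter (4).
#' @param update_interval controller update period, seconds (0.025).
#' @param history_window length of past data used per update, seconds (3).
#' @param pad zero-padding added to each end before filtering, seconds (1).
#' @param gating_delay envelope read-out lag from the window end, seconds
#'   (0.025), protecting the estimate from end-of-window edge effects.
#' @param threshold_percentile envelope percentile of the baseline run that
#'   gates stimulation (75).
#' @param stim_duration stimulation epoch length, seconds (0.5).
#' @param refractory quiet period required after an epoch, seconds (0.5);
#'   onsets are therefore at least `stim_duration + refractory` apart.
#' @param assumed_freq frequency assumed when extrapolating phase from the
#'   last positive zero-crossing, Hz (18, the passband centre).
#' @param amplitude_ratio stimulation amplitude as a fraction of the
#'   intrinsic noise standard deviation of `amplitude_ref` (default 1/4).
#' @param phase_shift target phase shift of the stimulus relative to the
#'   sensed oscillation, radians.
#' @param amplitude_ref population whose `noise_sd` scales the amplitude
#'   (default `"M2.MP"`, the cortical noise source; the superficial layer
#'   itself carries no intrinsic noise).
#' @param mode `"phaselock"` (default), `"fixed_freq"` (18 Hz sinusoid,
#'   gated but not phase-tracked) or `"playback"` (re-inject a recorded
#'   waveform).
#' @param threshold absolute gating threshold; computed from a baseline run
#'   when `NULL`.
#' @param fixed_phase0 phase offset of the free-running sinusoid in
#'   `fixed_freq` mode, radians.
#' @return List of class `cbgt_controller`.
#' @export
controller_config <- function(sense_source = "STN", stim_population = "M2.SP",
                              band = c(14, 21), filter_order = 4,
                              update_interval = 0.025, history_window = 3,
                              pad = 1, gating_delay = 0.025,
                              threshold_percentile = 75, stim_duration = 0.5,
                              refractory = 0.5, assumed_freq = 18,
                              amplitude_ratio = 0.25, phase_shift = 0,
                              amplitude_ref = "M2.MP",
                              mode = c("phaselock", "fixed_freq", "playback"),
                              threshold = NULL, fixed_phase0 = 0) {
  mode <- match.arg(mode)
  if (update_interval > stim_duration)
    stop("update_interval must not exceed stim_duration")
  if (history_window < 4 / band[1])
    stop("history_window must cover several periods of the band")
  if (threshold_percentile <= 0 || threshold_percentile >= 100)
    stop("threshold_percentile must be in (0, 100)")
  structure(list(sense_source = sense_source,
                 stim_population = stim_population, band = band,
                 filter_order = filter_order,
                 update_interval = update_interval,
                 history_window = history_window, pad = pad,
                 gating_delay = gating_delay,
                 threshold_percentile = threshold_percentile,
                 stim_duration = stim_duration, refractory = refractory,
                 assumed_freq = assumed_freq,
                 amplitude_ratio = amplitude_ratio, phase_shift = phase_shift,
                 amplitude_ref = amplitude_ref, mode = mode,
                 threshold = threshold, fixed_phase0 = fixed_phase0),
            class = "cbgt_controller")
}

#' On-line phase and envelope estimate
#'
#' One controller update: the sensing window (the past `history_window`
#' seconds) is zero-padded by `pad` seconds on each side, band-passed with a
#' zero-phase Butterworth filter, and the analytic envelope is formed. The
#' envelope is read out `gating_delay` before the window end (where the
#' estimate is stable); the current phase is extrapolated from the most
#' recent positive zero-crossing occurring before (window end -
#' `gating_delay`), assuming an `assumed_freq` sinusoid.
#'
#' @param window numeric vector of sense samples at `fs`, length
#'   `history_window * fs`.
#' @param cfg a [controller_config()].
#' @param fs sampling rate of the window, Hz.
#' @return List with `phase_now` (radians at the window end; `NA` when no
#'   positive zero-crossing is found), `envelope` (gated read-out value),
#'   `t_zc` (zero-crossing time relative to the window start, seconds),
#'   `available` (logical).
#' @export
online_phase_envelope <- function(window, cfg, fs) {
  n <- length(window)
  if (n != round(cfg$history_window * fs))
    stop("window length must equal history_window * fs")
  npad <- round(cfg$pad * fs)
  # mean-subtract before zero-padding so the pad boundaries carry no DC step
  window <- window - mean(window)
  padded <- c(numeric(npad), window, numeric(npad))
  filt <- bp_filtfilt(padded, cfg$band, fs, cfg$filter_order)
  z <- analytic_signal(filt)
  env <- Mod(z)[(npad + 1):(npad + n)]
  f <- filt[(npad + 1):(npad + n)]
  lag <- round(cfg$gating_delay * fs)
  gated_env <- env[n - lag]
  # positive-going zero crossings with sub-sample interpolation
  limit <- n - lag
  i <- which(f[-n] < 0 & f[-1] >= 0)
  i <- i[i + 1 <= limit]
  if (length(i) == 0L)
    return(list(phase_now = NA_real_, envelope = gated_env, t_zc = NA_real_,
                available = FALSE))
  i <- max(i)
  frac <- -f[i] / (f[i + 1] - f[i])
  t_zc <- (i - 1 + frac) / fs
  t_end <- (n - 1) / fs
  phase_now <- wrap_phase(2 * pi * cfg$assumed_freq * (t_end - t_zc))
  list(phase_now = phase_now, envelope = gated_env, t_zc = t_zc,
       available = TRUE)
}

#' Stimulation gating decision
#'
#' TRUE iff the gated envelope strictly exceeds the baseline threshold
#' (criterion A) and the time since the last stimulation onset is at least
#' `stim_duration + refractory` (criterion B).
#'
#' @param envelope gated envelope value.
#' @param threshold absolute threshold from the baseline run.
#' @param last_stim time of the last stimulation onset, seconds (`-Inf` if
#'   none).
#' @param now current time, seconds.
#' @param cfg a [controller_config()].
#' @return Logical.
#' @export
gate_stim <- function(envelope, threshold, last_stim, now, cfg) {
  isTRUE(envelope > threshold) &&
    (now - last_stim) >= cfg$stim_duration + cfg$refractory
}

#' Instantaneous stimulation value
#'
#' `A * sin(phase_now + phase_shift)` when the gating criteria hold, else 0.
#'
#' @param phase_now estimated phase of the sensed oscillation, radians.
#' @param cfg a [controller_config()].
#' @param crit logical gating decision.
#' @param amplitude stimulation amplitude A (defaults to
#'   `amplitude_ratio` - see [controller_config()] - times 1, for unit
#'   noise; the closed-loop driver passes the circuit-derived value).
#' @return Injected input value.
#' @export
stim_waveform <- function(phase_now, cfg, crit, amplitude = cfg$amplitude_ratio) {
  if (!crit) return(0)
  amplitude * sin(phase_now + cfg$phase_shift)
}

#' Gating threshold from a baseline run
#'
#' Band-limited analytic envelope of the baseline sensing channel (same band
#' and filter order as the controller, computed on the controller's
#' subsampled view of the signal), summarized at the configured percentile
#' with linear interpolation.
#'
#' @param baseline a [simulate_cbgt()] result without stimulation.
#' @param cfg a [controller_config()].
#' @return Scalar threshold.
#' @export
baseline_threshold <- function(baseline, cfg) {
  i <- match(cfg$sense_source, rownames(baseline$subsampled))
  x <- as.numeric(baseline$subsampled[i, ])
  env <- bandpass_hilbert(x, cfg$band, baseline$fs, cfg$filter_order)$amp
  pct_threshold(env, cfg$threshold_percentile)
}

stim_amplitude <- function(circuit, cfg) {
  p <- circuit$populations
  sd_ref <- p$noise_sd[match(cfg$amplitude_ref, p$id)]
  cfg$amplitude_ratio * sd_ref
}

#' Closed-loop (or control-policy) stimulated simulation
#'
#' Re-simulates the circuit with the identical noise realization as the
#' baseline run while the controller senses the STN at the output rate,
#' updates every `update_interval`, and injects the stimulation waveform
#' into the stimulated population's input between updates. In `phaselock`
#' mode the injected sinusoid is extrapolated from the current phase
#' estimate; in `fixed_freq` mode it free-runs at `assumed_freq`; in
#' `playback` mode a previously recorded waveform is injected verbatim
#' (into a run with whatever noise realization is supplied).
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param config a [sim_config()] object.
#' @param cfg a [controller_config()].
#' @param noise optional pre-drawn noise matrix (to share the baseline's
#'   realization); defaults to a draw from `config$seed`.
#' @param playback_record a stimulation record whose `waveform` is re-used in
#'   `playback` mode (longer records are truncated with a warning).
#' @return A [ts_set()] with element `stim_record`: list with `stim_onsets`
#'   (seconds, absolute simulation time), `waveform` (per raw integration
#'   step), `phase_estimates`, `gate_log` (per-update data frame with the
#'   envelope, both gating criteria and the stimulating flag), `amplitude`,
#'   `threshold`, `cfg`.
#' @export
simulate_stimulation <- function(circuit, config, cfg, noise = NULL,
                                 playback_record = NULL) {
  prep <- sim_prepare(circuit, config)
  if (is.null(noise)) noise <- sim_noise(config, prep$n_raw)
  dt <- config$dt
  stim_pop <- match(cfg$stim_population, circuit$populations$id)
  amplitude <- stim_amplitude(circuit, cfg)
  meta <- list(seed = config$seed, config = unclass(config),
               controller = unclass(cfg))

  if (cfg$mode == "playback") {
    if (is.null(playback_record)) stop("playback mode needs a record")
    w <- playback_record$waveform
    if (length(w) > prep$n_raw) {
      warning("playback record longer than the run: truncated")
      w <- w[seq_len(prep$n_raw)]
    }
    stim <- c(w, numeric(prep$n_raw - length(w)))
    vbuf <- matrix(0, prep$n_raw, 9L)
    state <- list(v = numeric(9), vdot = numeric(9))
    sim_run_chunk(prep, vbuf, state, 0L, prep$n_raw, noise, stim, stim_pop, dt)
    out <- sim_finalize(vbuf, circuit, config, prep, meta)
    out$stim_record <- list(stim_onsets = playback_record$stim_onsets,
                            waveform = stim, phase_estimates = NULL,
                            gate_log = NULL, amplitude = amplitude,
                            threshold = NA_real_, cfg = cfg)
    return(out)
  }

  threshold <- cfg$threshold
  if (is.null(threshold)) {
    baseline <- simulate_cbgt(circuit, config, noise = noise)
    threshold <- baseline_threshold(baseline, cfg)
  }

  fs <- config$out_rate
  decim <- prep$decim
  upd <- as.integer(round(cfg$update_interval / dt))
  hist_n <- as.integer(round(cfg$history_window * fs))
  start_t <- config$burn_in + cfg$history_window
  vbuf <- matrix(0, prep$n_raw, 9L)
  state <- list(v = numeric(9), vdot = numeric(9))
  stim <- numeric(prep$n_raw)
  sense_idx <- match(cfg$sense_source, cbgt_sources())
  obs_pop <- match(circuit$observation_map[[sense_idx]],
                   circuit$populations$id)

  onsets <- numeric(0)
  last_onset <- -Inf
  epoch_end <- -Inf
  phase_ref <- NULL   # list(phase, time) of the last valid estimate
  log_rows <- list()
  phase_est <- numeric(0)

  s <- 0L
  while (s < prep$n_raw) {
    nstep <- min(upd, prep$n_raw - s)
    t_now <- s * dt
    # decide the waveform for the next chunk before integrating it
    if (t_now >= start_t) {
      j <- s %/% decim
      win <- vbuf[seq.int((j - hist_n) * decim + decim, j * decim,
                          by = decim), obs_pop]
      est <- online_phase_envelope(win, cfg, fs)
      if (est$available) phase_ref <- list(phase = est$phase_now, time = t_now)
      critA <- isTRUE(est$envelope > threshold)
      critB <- (t_now - last_onset) >= cfg$stim_duration + cfg$refractory
      want <- gate_stim(est$envelope, threshold, last_onset, t_now, cfg)
      if (want && t_now >= epoch_end &&
          (cfg$mode == "fixed_freq" || !is.null(phase_ref))) {
        last_onset <- t_now
        epoch_end <- t_now + cfg$stim_duration
        onsets <- c(onsets, t_now)
      }
      stimulating <- t_now < epoch_end
      if (stimulating) {
        tau <- dt * seq_len(nstep)
        if (cfg$mode == "fixed_freq") {
          ph <- 2 * pi * cfg$assumed_freq * (t_now + tau) + cfg$fixed_phase0
        } else {
          ph <- phase_ref$phase +
            2 * pi * cfg$assumed_freq * (t_now + tau - phase_ref$time)
        }
        seg <- amplitude * sin(ph + cfg$phase_shift)
        seg[t_now + tau > epoch_end] <- 0
        stim[(s + 1):(s + nstep)] <- seg
      }
      phase_est <- c(phase_est, if (est$available) est$phase_now else NA_real_)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(time = t_now, envelope = est$envelope,
                   phase = if (est$available) est$phase_now else NA_real_,
                   critA = critA, critB = critB, stimulating = stimulating)
    }
    sim_run_chunk(prep, vbuf, state, s, nstep, noise, stim, stim_pop, dt)
    s <- s + nstep
  }
  out <- sim_finalize(vbuf, circuit, config, prep, meta)
  out$stim_record <- list(stim_onsets = onsets, waveform = stim,
                          phase_estimates = phase_est,
                          gate_log = do.call(rbind, log_rows),
                          amplitude = amplitude, threshold = threshold,
                          cfg = cfg)
  out
}

#' Stimulation epochs of a record
#' @param record `stim_record` element of a stimulated run.
#' @return Data frame with `onset`, `offset` in absolute simulation seconds.
#' @export
stim_epochs <- function(record) {
  data.frame(onset = record$stim_onsets,
             offset = record$stim_onsets + record$cfg$stim_duration)
}

#' Sweep stimulation phase
#'
#' Runs one baseline simulation (defining the gating threshold and the
#' shared noise realization) and then one stimulated run per target phase
#' shift, by default 12 phases at 30 degree spacing spanning the circle.
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param config a [sim_config()] object.
#' @param cfg a [controller_config()].
#' @param phases_deg target phase shifts in degrees (default
#'   `seq(-180, 150, by = 30)`).
#' @return List of class `cbgt_sweep` with `baseline`, `runs` (named by
#'   phase in degrees), `phases_deg`, `threshold`.
#' @export
run_phase_sweep <- function(circuit, config, cfg,
                            phases_deg = seq(-180, 150, by = 30)) {
  prep <- sim_prepare(circuit, config)
  noise <- sim_noise(config, prep$n_raw)
  baseline <- simulate_cbgt(circuit, config, noise = noise)
  threshold <- baseline_threshold(baseline, cfg)
  runs <- lapply(phases_deg, function(ph) {
    ci <- cfg
    ci$phase_shift <- ph * pi / 180
    ci$threshold <- threshold
    simulate_stimulation(circuit, config, ci, noise = noise)
  })
  names(runs) <- as.character(phases_deg)
  structure(list(baseline = baseline, runs = runs, phases_deg = phases_deg,
                 threshold = threshold),
            class = "cbgt_sweep")
}

#' Non-phase-specific control policies
#'
#' `fixed_freq`: an 18 Hz sinusoid gated by the usual envelope criteria but
#' with free-running (not phase-tracked) phase. `playback`: a stimulation
#' waveform recorded in one run injected into a run with a different noise
#' realization.
#'
#' @param circuit,config,cfg as in [simulate_stimulation()].
#' @param mode `"fixed_freq"` or `"playback"`.
#' @param playback_record record to replay in playback mode.
#' @param noise optional noise matrix.
#' @return A stimulated [ts_set()].
#' @export
control_policies <- function(circuit, config, cfg,
                             mode = c("fixed_freq", "playback"),
                             playback_record = NULL, noise = NULL) {
  cfg$mode <- match.arg(mode)
  simulate_stimulation(circuit, config, cfg, noise = noise,
                       playback_record = playback_record)
}

# within-epoch band power of one channel (mean squared band-passed signal
# over the epoch samples); epochs in absolute time, signal starts at burn_in
epoch_band_power <- function(ts, channel, epochs, band) {
  burn <- ts$meta$config$burn_in
  x <- bp_filtfilt(ts_channel(ts, channel), band, ts$fs)
  idx <- unlist(lapply(seq_len(nrow(epochs)), function(k) {
    i0 <- floor((epochs$onset[k] - burn) * ts$fs) + 1L
    i1 <- min(ncol(ts$data), round((epochs$offset[k] - burn) * ts$fs))
    if (i1 >= i0) i0:i1 else integer(0)
  }))
  mean(x[idx]^2)
}

epoch_matrix <- function(ts, channel, epochs) {
  burn <- ts$meta$config$burn_in
  x <- ts_channel(ts, channel)
  len <- min(round((epochs$offset - epochs$onset) * ts$fs))
  do.call(rbind, lapply(seq_len(nrow(epochs)), function(k) {
    i0 <- floor((epochs$onset[k] - burn) * ts$fs) + 1L
    x[i0:(i0 + len - 1L)]
  }))
}

#' Amplitude response curves
#'
#' Percentage change of band-limited power within stimulation epochs,
#' relative to the identical (duration-matched) windows of the unstimulated
#' baseline run, per target phase, signal and beta sub-band; plus the change
#' of M2/STN band coherence computed over the same epochs.
#'
#' @param sweep a [run_phase_sweep()] result.
#' @param bands named list of bands (default lower/upper beta).
#' @param signals channels to summarize (default M2 and STN).
#' @return List with `arc` (data frame: `phase_deg`, `signal`, `band`,
#'   `pct_change`; `NA` where a condition delivered no stimulation) and
#'   `coherence` (data frame: `phase_deg`, `band`, `pct_change`).
#' @export
amplitude_response_curves <- function(sweep,
                                      bands = list(beta1 = c(14, 21),
                                                   beta2 = c(21, 30)),
                                      signals = c("M2", "STN")) {
  arc <- list(); coh <- list()
  for (ph in sweep$phases_deg) {
    run <- sweep$runs[[as.character(ph)]]
    ep <- stim_epochs(run$stim_record)
    if (nrow(ep) == 0L) {
      warning("no stimulation delivered at phase ", ph, " deg")
      for (sg in signals) for (bn in names(bands))
        arc[[length(arc) + 1L]] <- data.frame(phase_deg = ph, signal = sg,
                                              band = bn,
                                              pct_change = NA_real_)
      next
    }
    for (sg in signals) for (bn in names(bands)) {
      p1 <- epoch_band_power(run, sg, ep, bands[[bn]])
      p0 <- epoch_band_power(sweep$baseline, sg, ep, bands[[bn]])
      arc[[length(arc) + 1L]] <- data.frame(phase_deg = ph, signal = sg,
                                            band = bn,
                                            pct_change = 100 * (p1 / p0 - 1))
    }
    for (bn in names(bands)) {
      e1a <- epoch_matrix(run, "M2", ep); e1b <- epoch_matrix(run, "STN", ep)
      e0a <- epoch_matrix(sweep$baseline, "M2", ep)
      e0b <- epoch_matrix(sweep$baseline, "STN", ep)
      cs1 <- cross_spectra(e1a, e1b, run$fs, ncol(e1a))
      cs0 <- cross_spectra(e0a, e0b, run$fs, ncol(e0a))
      nf <- ncol(e1a) %/% 2 + 1
      fr <- seq(0, run$fs / 2, length.out = nf)
      inb <- fr >= bands[[bn]][1] & fr <= bands[[bn]][2]
      c1 <- mean((Mod(cs1$fxy)^2 / (cs1$fxx * cs1$fyy))[seq_len(nf)][inb])
      c0 <- mean((Mod(cs0$fxy)^2 / (cs0$fxx * cs0$fyy))[seq_len(nf)][inb])
      coh[[length(coh) + 1L]] <- data.frame(phase_deg = ph, band = bn,
                                            pct_change = 100 * (c1 / c0 - 1))
    }
  }
  list(arc = do.call(rbind, arc), coherence = do.call(rbind, coh))
}
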