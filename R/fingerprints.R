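#' STN band power of a circuit configuration
#'
#' Welch band power (integrated spectral density) of the simulated STN
#' signal, averaged over fixed seeds; the quantity on which the network
#' states are calibrated.
#'
#' @param circuit a [cbgt_circuit()] object.
#' @param band `c(low, high)` Hz (default broadband beta, 14-30 Hz).
#' @param seeds integer seeds averaged over (default 1:3).
#' @param duration seconds simulated per seed (default 60, excluding the
#'   burn-in which is added on top).
#' @return Mean band power across seeds.
#' @export
stn_beta_power <- function(circuit, band = c(14, 30), seeds = 1:3,
                           duration = 60) {
  mean(vapply(seeds, function(sd) {
    cfg <- sim_config(duration = duration + 2, seed = sd)
    sim <- simulate_cbgt(circuit, cfg)
    ps <- welch_psd(ts_channel(sim, "STN"), sim$fs)
    df <- diff(ps$freqs[1:2])
    sum(ps$psd[ps$freqs >= band[1] & ps$freqs <= band[2]]) * df
  }, 1))
}

#' Define a discrete network state
#'
#' Down-regulated states fix the pathway weight at 30% of the fitted value.
#' Up-regulated states are calibrated by bisection on the weight multiplier
#' until the STN broadband beta (14-30 Hz) power reaches `target_ratio`
#' times the unmodulated model's power (within `tol`, averaged over fixed
#' seeds with at least 60 s simulated per evaluation).
#'
#' @param circuit the fitted circuit.
#' @param pathway `"HD"` or `"PS"`.
#' @param mode `"up"` or `"down"`.
#' @param target_ratio beta power ratio targeted by the Up calibration
#'   (default 2.0, i.e. a doubling).
#' @param tol relative stopping tolerance on the ratio (default 0.05).
#' @param seeds seeds averaged per evaluation (default 1:3).
#' @param duration seconds simulated per seed per evaluation (default 60).
#' @param down_multiplier weight fraction of the Down states (default 0.30).
#' @param search multiplier bracket for the Up calibration (default
#'   `c(1, 6)`).
#' @return List of class `cbgt_state`: `name`, `pathway`, `mode`,
#'   `multiplier`, `circuit` (modified), `provenance` (fixed, or the
#'   calibration record with the achieved ratio).
#' @export
define_state <- function(circuit, pathway = c("HD", "PS"),
                         mode = c("up", "down"), target_ratio = 2.0,
                         tol = 0.05, seeds = 1:3, duration = 60,
                         down_multiplier = 0.30, search = c(1, 6)) {
  pathway <- match.arg(pathway)
  mode <- match.arg(mode)
  name <- paste0(pathway, "-", if (mode == "up") "Up" else "Down")
  if (mode == "down") {
    circ <- set_pathway_weight(circuit, pathway, down_multiplier)
    return(structure(list(name = name, pathway = pathway, mode = mode,
                          multiplier = down_multiplier, circuit = circ,
                          provenance = list(kind = "fixed")),
                     class = "cbgt_state"))
  }
  base_power <- stn_beta_power(circuit, seeds = seeds, duration = duration)
  ratio_at <- function(m) {
    stn_beta_power(set_pathway_weight(circuit, pathway, m),
                   seeds = seeds, duration = duration) / base_power
  }
  lo <- search[1]; hi <- search[2]
  r_lo <- ratio_at(lo)
  if (abs(r_lo - target_ratio) <= tol * target_ratio) {
    m <- lo; achieved <- r_lo
  } else {
    r_hi <- ratio_at(hi)
    if ((r_lo - target_ratio) * (r_hi - target_ratio) > 0)
      stop(sprintf(paste0("calibration failed to bracket the target ratio ",
                          "%.2f in multiplier range [%g, %g]: achieved ",
                          "%.2f and %.2f"),
                   target_ratio, lo, hi, r_lo, r_hi))
    achieved <- NA_real_
    for (it in seq_len(30)) {
      m <- (lo + hi) / 2
      r <- ratio_at(m)
      if (abs(r - target_ratio) <= tol * target_ratio) { achieved <- r; break }
      if ((r - target_ratio) * (r_lo - target_ratio) > 0) {
        lo <- m; r_lo <- r
      } else hi <- m
      achieved <- r
    }
  }
  circ <- set_pathway_weight(circuit, pathway, m)
  structure(list(name = name, pathway = pathway, mode = mode, multiplier = m,
                 circuit = circ,
                 provenance = list(kind = "calibrated",
                                   target_ratio = target_ratio, tol = tol,
                                   seeds = seeds, duration = duration,
                                   achieved_ratio = achieved,
                                   base_power = base_power)),
            class = "cbgt_state")
}

#' @export
print.cbgt_state <- function(x, ...) {
  cat(sprintf("<cbgt_state> %s: %s pathway multiplier %.3f (%s)\n",
              x$name, x$pathway, x$multiplier, x$provenance$kind))
  invisible(x)
}

as_intervals <- function(x) {
  if (inherits(x, "cbgt_bursts")) x$intervals else as.data.frame(x)
}

#' Spectral fingerprint of a run
#'
#' Summarizes network activity inside the given windows (STN bursts for
#' spontaneous activity; stimulation epochs for stimulated runs) with two
#' feature blocks: (a) per-source Welch spectra of the concatenated
#' within-window samples, truncated to 2-48 Hz and normalized to unit
#' variance per source before concatenation, and (b) the pairwise
#' within-window PLV matrices at lower and upper beta.
#'
#' @param ts a [ts_set()] object.
#' @param windows a [detect_bursts()] object or a data frame with
#'   `onset`/`offset` in seconds relative to the signal start.
#' @param spectra_exclude sources excluded from the spectral block (e.g.
#'   `c("GPi", "Thal")` for comparisons against empirical data).
#' @param plv_sources sources retained in the PLV block (default all).
#' @param frange spectral range, Hz (default `c(2, 48)`).
#' @param bands named list of PLV bands (default beta1/beta2).
#' @return Object of class `cbgt_fingerprint`: `spectra` (named list of
#'   unit-variance spectral blocks), `freqs`, `plv` (named list of PLV
#'   matrices), `masks`.
#' @export
build_fingerprint <- function(ts, windows, spectra_exclude = character(0),
                              plv_sources = NULL, frange = c(2, 48),
                              bands = list(beta1 = c(14, 21),
                                           beta2 = c(21, 30))) {
  iv <- as_intervals(windows)
  if (nrow(iv) == 0L) stop("no windows (bursts) to build a fingerprint from")
  fs <- ts$fs
  n <- ncol(ts$data)
  pseudo <- structure(list(intervals = iv, fs = fs), class = "cbgt_bursts")
  mask <- burst_mask(pseudo, n, fs)
  if (sum(mask) < fs) stop("fewer than one second of within-window samples")
  seg_len <- round(fs)
  spec_sources <- setdiff(ts$labels, spectra_exclude)
  spectra <- list()
  freqs <- NULL
  for (lb in spec_sources) {
    x <- ts_channel(ts, lb)[mask]
    ps <- welch_psd(x, fs, seg_len)
    sel <- ps$freqs >= frange[1] & ps$freqs <= frange[2]
    blk <- ps$psd[sel]
    spectra[[lb]] <- blk / stats::sd(blk)
    freqs <- ps$freqs[sel]
  }
  if (is.null(plv_sources)) plv_sources <- ts$labels
  sub <- ts_set(ts$data[plv_sources, , drop = FALSE], plv_sources, fs,
                ts$meta)
  plvs <- lapply(bands, function(b) within_burst_plv(sub, pseudo, b)$values)
  structure(list(spectra = spectra, freqs = freqs, plv = plvs,
                 masks = list(spectra_exclude = spectra_exclude,
                              plv_sources = plv_sources)),
            class = "cbgt_fingerprint")
}

fingerprint_block <- function(fp, what) {
  if (what == "spectra") return(unlist(fp$spectra, use.names = FALSE))
  unlist(lapply(fp$plv, function(m) m[upper.tri(m)]), use.names = FALSE)
}

#' Pooled R-squared between two fingerprints
#'
#' `1 - (1/Nf) * sum_n [ sum_i (y_state - y_stim)^2 / sum_i
#' (y_stim - mean(y_stim))^2 ]` over the included feature blocks
#' (concatenated spectra and/or flattened PLV matrices). 1 indicates a
#' perfect match; negative values indicate a fit worse than the stimulated
#' features' own mean.
#'
#' @param fp_state,fp_stim [build_fingerprint()] objects with matching
#'   masks and grids.
#' @param features blocks to include: subset of `c("spectra", "plv")`.
#' @return Scalar in (-Inf, 1].
#' @export
pooled_r2 <- function(fp_state, fp_stim, features = c("spectra", "plv")) {
  stopifnot(identical(fp_state$masks, fp_stim$masks),
            identical(fp_state$freqs, fp_stim$freqs))
  features <- match.arg(features, c("spectra", "plv"), several.ok = TRUE)
  terms <- vapply(features, function(ft) {
    ys <- fingerprint_block(fp_state, ft)
    yt <- fingerprint_block(fp_stim, ft)
    stopifnot(length(ys) == length(yt))
    den <- sum((yt - mean(yt))^2)
    if (den == 0)
      stop("constant feature block '", ft, "': pooled R2 undefined")
    sum((ys - yt)^2) / den
  }, 1)
  1 - mean(terms)
}

stim_windows_rel <- function(run) {
  ep <- stim_epochs(run$stim_record)
  burn <- run$meta$config$burn_in
  data.frame(onset = pmax(0, ep$onset - burn), offset = ep$offset - burn)
}

#' State recovery across stimulation phases
#'
#' For every phase condition of a sweep, builds the fingerprint of the data
#' within stimulation epochs and scores it against each predefined network
#' state's fingerprint with the pooled R-squared, using spectra only, PLV
#' only, and both combined.
#'
#' @param sweep a [run_phase_sweep()] result.
#' @param state_fps named list of state fingerprints (from
#'   [build_fingerprint()] on unstimulated state runs).
#' @param realign logical: additionally report phases realigned so the
#'   phase of maximum combined recovery of the first state maps to 0.
#' @param ... masks/bands forwarded to [build_fingerprint()].
#' @return List with `r2` (array phases x states x feature sets), the
#'   `phases_deg`, and optionally `realigned_phases_deg`.
#' @export
recovery_sweep <- function(sweep, state_fps, realign = FALSE, ...) {
  phases <- sweep$phases_deg
  fsets <- c("spectra", "plv", "combined")
  r2 <- array(NA_real_, c(length(phases), length(state_fps), length(fsets)),
              dimnames = list(as.character(phases), names(state_fps), fsets))
  for (k in seq_along(phases)) {
    run <- sweep$runs[[as.character(phases[k])]]
    if (is.null(run)) stop("missing phase condition: ", phases[k])
    fp <- build_fingerprint(run, stim_windows_rel(run), ...)
    for (s in seq_along(state_fps)) {
      r2[k, s, "spectra"] <- pooled_r2(state_fps[[s]], fp, "spectra")
      r2[k, s, "plv"] <- pooled_r2(state_fps[[s]], fp, "plv")
      r2[k, s, "combined"] <- pooled_r2(state_fps[[s]], fp,
                                        c("spectra", "plv"))
    }
  }
  out <- list(r2 = r2, phases_deg = phases)
  if (realign) {
    best <- phases[which.max(r2[, 1, "combined"])]
    out$realigned_phases_deg <- ((phases - best + 180) %% 360) - 180
  }
  out
}

#' Recovery over connection strength and stimulation phase
#'
#' Repeats the phase sweep at a grid of pathway connection strengths
#' (from the Down-state fraction up to the calibrated Up-state multiplier)
#' and scores pooled R-squared against each state, yielding the heatmap
#' grid of recoverable states plus the best-matching state per cell.
#'
#' @param circuit the fitted circuit.
#' @param pathway `"HD"` or `"PS"`.
#' @param strengths multiplier grid (e.g. `seq(0.3, up_multiplier,
#'   length.out = 5)`).
#' @param config a [sim_config()].
#' @param cfg a [controller_config()].
#' @param state_fps named list of state fingerprints.
#' @param phases_deg phase grid (default 12 x 30 degrees).
#' @param features feature set for the best-state map (default "combined").
#' @param ... forwarded to [build_fingerprint()].
#' @return List with `r2` (array strengths x phases x states x feature
#'   sets), `best_state` (matrix strengths x phases), `strengths`,
#'   `phases_deg`.
#' @export
strength_phase_heatmap <- function(circuit, pathway, strengths, config, cfg,
                                   state_fps,
                                   phases_deg = seq(-180, 150, by = 30),
                                   features = "combined", ...) {
  fsets <- c("spectra", "plv", "combined")
  r2 <- array(NA_real_, c(length(strengths), length(phases_deg),
                          length(state_fps), length(fsets)),
              dimnames = list(as.character(strengths),
                              as.character(phases_deg), names(state_fps),
                              fsets))
  best <- matrix(NA_character_, length(strengths), length(phases_deg),
                 dimnames = list(as.character(strengths),
                                 as.character(phases_deg)))
  for (i in seq_along(strengths)) {
    circ_i <- set_pathway_weight(circuit, pathway, strengths[i])
    sweep <- run_phase_sweep(circ_i, config, cfg, phases_deg)
    rec <- recovery_sweep(sweep, state_fps, ...)
    r2[i, , , ] <- rec$r2
    for (j in seq_along(phases_deg))
      best[i, j] <- names(state_fps)[which.max(rec$r2[j, , features])]
  }
  list(r2 = r2, best_state = best, strengths = strengths,
       phases_deg = phases_deg)
}
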