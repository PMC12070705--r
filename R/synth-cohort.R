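#' Generative blood-pressure law
#'
#' Linear law linking a window's generative waveform parameters to its
#' ground-truth pressures:
#' `BP = intercept + b_ptt / PTT + b_ai * AI + b_hr * HR + noise`.
#' The inverse-PTT term carries most of the signal (shorter transit time,
#' higher pressure); the augmentation-index term adds an arterial-stiffness
#' contribution; the heart-rate term encodes the sympathetic coupling that
#' makes an acute heart-rate rise co-occur with a systolic rise. Default
#' coefficients are calibrated so that, under the default subject
#' distributions, SBP ~ 122 +/- 12 mmHg and DBP ~ 75 +/- 8 mmHg, matching a
#' young mostly-male smoking cohort.
#'
#' @param sbp,dbp Named numeric vectors with elements `intercept`, `inv_ptt`,
#'   `ai`, `hr`.
#' @return A `bp_law` list.
#' @export
bp_law <- function(sbp = c(intercept = -3.5, inv_ptt = 25, ai = 5, hr = 0.15),
                   dbp = c(intercept = 3.5, inv_ptt = 15, ai = 3, hr = 0.05)) {
  need <- c("intercept", "inv_ptt", "ai", "hr")
  if (!all(need %in% names(sbp)) || !all(need %in% names(dbp))) {
    stop_invalid("bp_law coefficients need names intercept, inv_ptt, ai, hr")
  }
  if (all(c(sbp, dbp) == 0)) {
    warning("degenerate bp_law: all coefficients are zero")
  }
  structure(list(sbp = sbp[need], dbp = dbp[need]), class = "bp_law")
}

#' Apply a BP law to generative parameters
#'
#' @param law A [bp_law()].
#' @param ptt Pulse transit time in seconds.
#' @param ai Augmentation index (systolic/diastolic wave amplitude ratio).
#' @param hr Heart rate in bpm.
#' @return A list with numeric elements `sbp` and `dbp` in mmHg (noise-free;
#'   callers add observation noise).
#' @export
apply_bp_law <- function(law, ptt, ai, hr) {
  one <- function(cf) {
    unname(cf["intercept"] + cf["inv_ptt"] / ptt + cf["ai"] * ai + cf["hr"] * hr)
  }
  list(sbp = one(law$sbp), dbp = one(law$dbp))
}

#' Generate a synthetic feature cohort with known blood pressures
#'
#' Draws `n_subjects` subjects (heart rate, transit time, beat morphology
#' from the cohort distributions below), renders one paired PPG/ECG record
#' per subject and phase, runs the full conditioning / fiducial-detection /
#' feature-extraction pipeline on each record, and attaches ground-truth
#' SBP/DBP computed from the generative law on the record's true PTT,
#' augmentation index, and heart rate, plus Gaussian observation noise.
#'
#' Subject draws (truncated normals): heart rate 83.2 +/- 12.6 bpm in
#' \[55, 115\]; PTT 0.25 +/- 0.03 s in \[0.18, 0.32\]; diastolic/systolic
#' amplitude ratio 0.45 +/- 0.05 in \[0.32, 0.60\]; systolic width
#' 0.05 +/- 0.004 s; diastolic width 0.09 +/- 0.006 s.
#'
#' @param n_subjects Number of subjects (>= 2); one row is produced per
#'   subject and phase.
#' @param phases List of [phase_preset()]s (default: baseline only).
#' @param law A [bp_law()].
#' @param bp_noise_sd Observation-noise standard deviation added to both
#'   pressures, in mmHg.
#' @param duration,fs Record length (s) and sampling rate (Hz).
#' @param feature_preset Feature registry preset for the rows (default
#'   `"full"`, which includes the PTT statistics the law depends on).
#' @param rng_seed Root seed; per-subject seeds come from [derive_seed()].
#' @return A `data.frame` (cohort table) with columns `subject_id`, `habit`,
#'   `phase`, `provenance`, `sbp_ref`, `dbp_ref` and one column per feature,
#'   plus a `truth` attribute holding the generative parameters per row.
#' @export
generate_cohort <- function(n_subjects = 84, phases = phase_presets("before"),
                            law = bp_law(), bp_noise_sd = 2,
                            duration = 30, fs = 500,
                            feature_preset = "full", rng_seed = 1L) {
  if (n_subjects < 2) stop_invalid("`n_subjects` must be >= 2")
  if (inherits(phases, "phase_preset")) phases <- list(phases)
  rows <- vector("list", n_subjects * length(phases))
  truth <- vector("list", length(rows))
  ri <- 0L
  for (i in seq_len(n_subjects)) {
    seed_i <- derive_seed(rng_seed, i)
    subj <- withr::with_seed(seed_i, {
      list(
        hr = clamp(stats::rnorm(1, 83.24, 12.61), 55, 115),
        ptt = clamp(stats::rnorm(1, 0.25, 0.03), 0.18, 0.32),
        damp = clamp(stats::rnorm(1, 0.45, 0.05), 0.32, 0.60),
        ws = clamp(stats::rnorm(1, 0.05, 0.004), 0.04, 0.065),
        wd = clamp(stats::rnorm(1, 0.09, 0.006), 0.07, 0.11),
        # subject traits: habitual modulation/drift level and the gain of
        # the acute smoking response (responders vs non-responders)
        depth_jit = stats::rnorm(1, 0, 0.08),
        drift_jit = stats::rnorm(1, 0, 0.04),
        response = clamp(stats::rnorm(1, 1, 0.25), 0.4, 1.6),
        habit = sample(c("NC", "EC", "SH"), 1),
        cls = sample(c("LS", "MS", "HS", "HSS"), 1),
        bp_eps = stats::rnorm(2 * length(phases), 0, bp_noise_sd)
      )
    })
    ai_gen <- 1 / subj$damp
    for (p in seq_along(phases)) {
      base <- phases[[p]]
      preset <- phase_preset(
        base$phase,
        hr_shift = base$hr_shift * subj$response,
        amp_modulation_depth = clamp(base$amp_modulation_depth + subj$depth_jit,
                                     0.02, 0.6),
        notch_shift = base$notch_shift,
        baseline_drift_amp = clamp(base$baseline_drift_amp + subj$drift_jit,
                                   0.01, 0.3),
        ptt_shift = base$ptt_shift * subj$response
      )
      ri <- ri + 1L
      ctrl <- synth_control(
        beat = beat_model(diastolic_amp = subj$damp,
                          systolic_width = subj$ws,
                          diastolic_width = subj$wd),
        ptt = subj$ptt
      )
      hr_ph <- subj$hr + preset$hr_shift
      ptt_ph <- subj$ptt + preset$ptt_shift
      bp <- apply_bp_law(law, ptt_ph, ai_gen, hr_ph)
      sbp <- bp$sbp + subj$bp_eps[2 * p - 1]
      dbp <- bp$dbp + subj$bp_eps[2 * p]
      spec <- subject_spec(sprintf("S%03d", i), habit = subj$habit,
                           smoker_class = subj$cls, baseline_hr = subj$hr,
                           baseline_sbp = sbp, baseline_dbp = min(dbp, sbp - 1),
                           rng_seed = derive_seed(seed_i, p))
      rec <- generate_record(spec, preset, duration = duration, fs = fs,
                             control = ctrl)
      feats <- extract_window_features(rec, preset = feature_preset)
      rows[[ri]] <- cbind(
        data.frame(subject_id = spec$subject_id, habit = subj$habit,
                   phase = preset$phase, provenance = "measured",
                   sbp_ref = sbp, dbp_ref = dbp,
                   stringsAsFactors = FALSE),
        feats
      )
      truth[[ri]] <- data.frame(subject_id = spec$subject_id,
                                phase = preset$phase, ptt = ptt_ph,
                                ai = ai_gen, hr = hr_ph,
                                sbp_clean = bp$sbp, dbp_clean = bp$dbp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Write / read a cohort table as CSV
#'
#' Header order is `subject_id, habit, phase, provenance, sbp_ref, dbp_ref`
#' followed by the feature columns in registry order.
#'
#' @param table A cohort table.
#' @param path File path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sbp_ref", "dbp_ref"), names(df))
  if (length(miss) > 0) {
    stop_schema(paste("cohort file missing columns:", paste(miss, collapse = ", ")))
  }
  df
}
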