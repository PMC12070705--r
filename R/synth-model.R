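#' Two-Gaussian pulse beat model
#'
#' One PPG beat is rendered as the sum of a systolic and a diastolic Gaussian
#' wave over the beat period. The dicrotic notch is the local minimum of the
#' sum between the two wave centers, so every morphological landmark used by
#' the feature set (foot, systolic peak, notch, diastolic peak) exists
#' analytically and its ground-truth index is known exactly at render time.
#'
#' Wave centers are fractions of the beat period (so morphology scales with
#' heart rate); widths are in seconds (so wave sharpness does not). Defaults
#' place the systolic peak near 22 % and the diastolic wave near 59 % of the
#' cycle with an amplitude ratio of 0.45, giving a clearly expressed notch at
#' roughly 40--45 % of the cycle, typical of a young-adult finger PPG.
#'
#' @param systolic_amp,diastolic_amp Wave amplitudes in a.u.
#'   (`diastolic_amp < systolic_amp`).
#' @param systolic_center,diastolic_center Wave centers as fractions of the
#'   beat period, `0 < systolic_center < diastolic_center < 1`.
#' @param systolic_width,diastolic_width Gaussian widths in seconds.
#' @param notch_offset Extra shift (fraction of beat period) applied to the
#'   diastolic center; phase presets add their `notch_shift` here to emulate
#'   notch relocation.
#' @return A `beat_model` list.
#' @export
beat_model <- function(systolic_amp = 1, diastolic_amp = 0.45,
                       systolic_center = 0.22, diastolic_center = 0.59,
                       systolic_width = 0.05, diastolic_width = 0.09,
                       notch_offset = 0) {
  if (!(systolic_center > 0 && systolic_center < diastolic_center &&
        diastolic_center + notch_offset < 1)) {
    stop_invalid("need 0 < systolic_center < diastolic_center (+ offset) < 1")
  }
  if (diastolic_amp >= systolic_amp) {
    stop_invalid("`diastolic_amp` must be smaller than `systolic_amp`")
  }
  if (systolic_width <= 0 || diastolic_width <= 0) {
    stop_invalid("wave widths must be positive")
  }
  structure(list(systolic_amp = systolic_amp, diastolic_amp = diastolic_amp,
                 systolic_center = systolic_center,
                 diastolic_center = diastolic_center,
                 systolic_width = systolic_width,
                 diastolic_width = diastolic_width,
                 notch_offset = notch_offset),
            class = "beat_model")
}

PHASE_LEVELS <- c("before", "during", "after_5", "after_10", "after_20",
                  "after_30", "after_40")

#' Smoking-phase preset
#'
#' Deterministic modifiers applied to a subject's baseline physiology in one
#' measurement phase: heart-rate shift, beat-amplitude modulation depth,
#' dicrotic-notch relocation, baseline (AC) drift amplitude, and pulse
#' transit time shift. The during-phase PTT shortening is the mechanism that
#' couples the presets to blood pressure through the generative law (acute
#' vasoconstriction stiffens the arterial path, so the pulse arrives
#' earlier and pressure rises).
#'
#' @param phase One of `"before"`, `"during"`, `"after_5"`, `"after_10"`,
#'   `"after_20"`, `"after_30"`, `"after_40"`.
#' @param hr_shift Heart-rate shift in bpm relative to baseline.
#' @param amp_modulation_depth Beat-to-beat amplitude modulation depth in
#'   \[0, 1).
#' @param notch_shift Diastolic-wave (and hence notch) shift as a fraction of
#'   the beat period. No quantitative magnitude is established for notch
#'   relocation; the nonzero defaults here are nominal small fractions.
#' @param baseline_drift_amp Amplitude of the slow baseline drift in a.u.
#' @param ptt_shift Pulse-transit-time shift in seconds (negative = earlier
#'   pulse arrival, higher pressure).
#' @return A `phase_preset` list.
#' @export
phase_preset <- function(phase, hr_shift = 0, amp_modulation_depth = 0.1,
                         notch_shift = 0, baseline_drift_amp = 0.05,
                         ptt_shift = 0) {
  phase <- match.arg(phase, PHASE_LEVELS)
  if (amp_modulation_depth < 0 || amp_modulation_depth >= 1) {
    stop_invalid("`amp_modulation_depth` must be in [0, 1)")
  }
  structure(list(phase = phase, hr_shift = hr_shift,
                 amp_modulation_depth = amp_modulation_depth,
                 notch_shift = notch_shift,
                 baseline_drift_amp = baseline_drift_amp,
                 ptt_shift = ptt_shift),
            class = "phase_preset")
}

#' Default presets for the seven protocol phases
#'
#' Baseline, during-smoking, and five post-smoking intervals (5/10/20/30/40
#' min). The during preset raises heart rate by 12 bpm (88 -> 100 bpm at the
#' default baseline), deepens amplitude modulation, relocates the notch, and
#' shortens PTT by 10 ms; the after-presets decay those effects toward
#' baseline without fully reaching it within 40 min. Nuisance effects
#' (modulation depth, drift) stay within about one subject-SD of the
#' baseline: amplitude fluctuation varies strongly between subjects and
#' habits, so the phases overlap rather than separate cleanly.
#'
#' @param phases Which phases to return (default: all seven, in protocol
#'   order).
#' @return Named list of [phase_preset()] objects.
#' @export
phase_presets <- function(phases = PHASE_LEVELS) {
  all <- list(
    before   = phase_preset("before",   0,  0.10, 0.000, 0.050,  0.000),
    during   = phase_preset("during",   12, 0.18, 0.030, 0.100, -0.010),
    after_5  = phase_preset("after_5",  8,  0.16, 0.020, 0.080, -0.006),
    after_10 = phase_preset("after_10", 6,  0.14, 0.015, 0.070, -0.004),
    after_20 = phase_preset("after_20", 4,  0.13, 0.010, 0.060, -0.003),
    after_30 = phase_preset("after_30", 2,  0.12, 0.005, 0.055, -0.002),
    after_40 = phase_preset("after_40", 1,  0.11, 0.000, 0.050, -0.001)
  )
  phases <- match.arg(phases, PHASE_LEVELS, several.ok = TRUE)
  all[phases]
}

#' Synthetic subject description
#'
#' @param subject_id Subject token (character).
#' @param habit Smoking habit: `"NC"` (cigarettes), `"EC"` (e-cigarettes), or
#'   `"SH"` (shisha).
#' @param smoker_class Consumption class: light/medium/heavy/excessive.
#' @param baseline_hr Resting heart rate in bpm, within \[40, 180\].
#' @param baseline_sbp,baseline_dbp Reference cuff pressures in mmHg
#'   (`SBP > DBP > 0`).
#' @param rng_seed Integer seed for this subject's record noise.
#' @return A `subject_spec` list.
#' @export
subject_spec <- function(subject_id, habit = c("NC", "EC", "SH"),
                         smoker_class = c("LS", "MS", "HS", "HSS"),
                         baseline_hr = 83, baseline_sbp = 122,
                         baseline_dbp = 75, rng_seed = 1L) {
  habit <- match.arg(habit)
  smoker_class <- match.arg(smoker_class)
  if (baseline_hr < 40 || baseline_hr > 180) {
    stop_invalid("`baseline_hr` must lie in [40, 180] bpm")
  }
  if (!(baseline_sbp > baseline_dbp && baseline_dbp > 0)) {
    stop_invalid("need baseline_sbp > baseline_dbp > 0")
  }
  structure(list(subject_id = as.character(subject_id), habit = habit,
                 smoker_class = smoker_class, baseline_hr = baseline_hr,
                 baseline_sbp = baseline_sbp, baseline_dbp = baseline_dbp,
                 rng_seed = as.integer(rng_seed)),
            class = "subject_spec")
}

#' Record-level nuisance and coupling parameters
#'
#' Everything about a record that is neither subject physiology nor phase
#' effect: the beat template, the R-peak-to-systolic-peak transit time, and
#' the noise model (mains interference, white noise, drift and modulation
#' frequencies, R-wave width).
#'
#' @param beat A [beat_model()].
#' @param ptt Pulse transit time in seconds from the ECG R-peak to the PPG
#'   systolic peak of the paired beat.
#' @param noise_sd White-noise standard deviation in a.u. (a clean finger
#'   PPG after conditioning sits near 0.5 % of pulse amplitude).
#' @param mains_amp 50 Hz interference amplitude in a.u.
#' @param mains_freq Interference frequency in Hz.
#' @param drift_freq Baseline-drift frequency in Hz.
#' @param mod_freq Amplitude-modulation frequency in Hz (respiratory-like).
#' @param r_width ECG R-wave Gaussian width in seconds.
#' @return A `synth_control` list.
#' @export
synth_control <- function(beat = beat_model(), ptt = 0.25, noise_sd = 0.005,
                          mains_amp = 0.02, mains_freq = 50,
                          drift_freq = 0.04, mod_freq = 0.1, r_width = 0.012) {
  if (ptt <= 0) stop_invalid("`ptt` must be positive")
  structure(list(beat = beat, ptt = ptt, noise_sd = noise_sd,
                 mains_amp = mains_amp, mains_freq = mains_freq,
                 drift_freq = drift_freq, mod_freq = mod_freq,
                 r_width = r_width),
            class = "synth_control")
}
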