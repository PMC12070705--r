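#' Generate one synthetic two-channel recording
#'
#' Renders a 30-s-style paired PPG/ECG record for one subject in one smoking
#' phase: a train of two-Gaussian PPG beats with amplitude modulation,
#' baseline drift, 50 Hz interference and white noise, and an ECG spike train
#' whose R-peaks precede the paired systolic peaks by the configured pulse
#' transit time. Ground-truth fiducial indices (foot, systolic peak, dicrotic
#' notch, diastolic peak) are taken from the rendered noise-free waveform, so
#' they are exact by construction and downstream detectors can be scored
#' against them.
#'
#' @param spec A [subject_spec()].
#' @param preset A [phase_preset()].
#' @param duration Record length in seconds (must hold at least two beats).
#' @param fs Sampling rate in Hz (>= 100).
#' @param control A [synth_control()] with the beat template, PTT, and noise
#'   model.
#' @return A `pw_record` list with elements `ppg`, `ecg` (both [pw_signal()])
#'   and `truth`: `beats` (data.frame of ground-truth indices per beat),
#'   `r_idx` (R-peak indices), and the generative parameters `hr`, `period`,
#'   `ptt`, `ai`.
#' @examples
#' rec <- generate_record(subject_spec("s1", baseline_hr = 88),
#'                        phase_presets("before")[[1]], duration = 10)
#' nrow(rec$truth$beats)
#' @export
generate_record <- function(spec, preset, duration = 30, fs = 500,
                            control = synth_control()) {
  stopifnot(inherits(spec, "subject_spec"), inherits(preset, "phase_preset"))
  if (fs < 100) stop_invalid("`fs` must be >= 100 Hz")
  hr <- spec$baseline_hr + preset$hr_shift
  if (hr <= 0) stop_invalid("effective heart rate must be positive")
  period <- 60 / hr
  if (duration < period) {
    stop_invalid("`duration` too short to hold one full beat")
  }
  n_beats <- floor(duration / period + 1e-9)
  if (n_beats < 2) stop_invalid("`duration` must hold at least two beats")

  ptt <- control$ptt + preset$ptt_shift
  if (ptt <= 0.02) stop_invalid("effective PTT must exceed 0.02 s")
  bm <- control$beat
  cs <- bm$systolic_center
  cd <- bm$diastolic_center + bm$notch_offset + preset$notch_shift
  if (cd <= cs || cd >= 1) stop_invalid("notch shift pushes waves out of the beat")

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  onsets <- (seq_len(n_beats) - 1) * period

  withr::with_seed(spec$rng_seed, {
    mod <- 1 + preset$amp_modulation_depth * sin(2 * pi * control$mod_freq * onsets)
    amp_s <- bm$systolic_amp * mod
    amp_d <- bm$diastolic_amp * mod

    y0 <- numeric(n)
    for (k in seq_len(n_beats)) {
      y0 <- y0 +
        amp_s[k] * exp(-(t - (onsets[k] + cs * period))^2 / (2 * bm$systolic_width^2)) +
        amp_d[k] * exp(-(t - (onsets[k] + cd * period))^2 / (2 * bm$diastolic_width^2))
    }

    drift_phi <- stats::runif(1, 0, 2 * pi)
    mains_phi <- stats::runif(1, 0, 2 * pi)
    ppg <- y0 +
      preset$baseline_drift_amp * sin(2 * pi * control$drift_freq * t + drift_phi) +
      control$mains_amp * sin(2 * pi * control$mains_freq * t + mains_phi) +
      stats::rnorm(n, 0, control$noise_sd)

    # R-peaks: one per beat, each preceding its paired systolic peak by ptt.
    # The pairing allows an R-peak whose pulse arrives after the record ends.
    r_times <- (0:n_beats) * period + cs * period - ptt
    r_times <- r_times[r_times >= 0 & r_times < duration]
    e0 <- numeric(n)
    for (rt in r_times) {
      e0 <- e0 + exp(-(t - rt)^2 / (2 * control$r_width^2))
    }
    ecg <- e0 +
      control$mains_amp * sin(2 * pi * control$mains_freq * t + mains_phi) +
      stats::rnorm(n, 0, control$noise_sd / 2)
  })

  truth_beats <- locate_truth(y0, fs, onsets, period, cs, cd, duration)
  ppg_sig <- pw_signal(ppg, fs, "PPG", subject = spec$subject_id,
                       phase = preset$phase)
  ecg_sig <- pw_signal(ecg, fs, "ECG", subject = spec$subject_id,
                       phase = preset$phase)
  structure(
    list(ppg = ppg_sig, ecg = ecg_sig,
         truth = list(beats = truth_beats,
                      r_idx = round(r_times * fs) + 1L,
                      hr = hr, period = period, ptt = ptt,
                      ai = bm$systolic_amp / bm$diastolic_amp,
                      clean_ppg = y0)),
    class = "pw_record"
  )
}

# Ground-truth landmarks from the noise-free rendered waveform. All indices
# are discrete argmin/argmax over the relevant sub-windows of the template.
locate_truth <- function(y0, fs, onsets, period, cs, cd, duration) {
  n <- length(y0)
  idx_of <- function(tt) as.integer(clamp(round(tt * fs) + 1, 1, n))
  n_beats <- length(onsets)
  mid <- (cs + cd) / 2

  peak_idx <- valley_idx <- notch_idx <- dia_idx <- integer(n_beats)
  for (k in seq_len(n_beats)) {
    o <- onsets[k]
    # systolic peak: maximum over the first part of the beat
    i1 <- idx_of(o); i2 <- idx_of(o + mid * period)
    peak_idx[k] <- i1 - 1L + which.max(y0[i1:i2])
    # foot: minimum between the previous diastolic wave and the systolic rise
    v1 <- idx_of(max(0, o - 0.3 * period))
    valley_idx[k] <- v1 - 1L + which.min(y0[v1:peak_idx[k]])
    # notch: first local minimum after the systolic peak that is followed by
    # a genuine diastolic rebound inside the beat
    e2 <- idx_of(min(o + period, duration))
    seg <- y0[peak_idx[k]:e2]
    notch_idx[k] <- NA_integer_; dia_idx[k] <- NA_integer_
    if (length(seg) >= 3) {
      d <- diff(seg)
      turns <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L # local minima
      if (length(turns) > 0) {
        cand <- turns[1]
        after <- seg[cand:length(seg)]
        rebound <- which.max(after)
        if (rebound > 1 && after[rebound] - after[1] > 1e-9) {
          notch_idx[k] <- peak_idx[k] - 1L + cand
          dia_idx[k] <- notch_idx[k] - 1L + rebound
        }
      }
    }
  }
  # the foot after the last beat closes the final pulse interval
  o_end <- onsets[n_beats] + period
  v1 <- idx_of(max(0, o_end - 0.3 * period))
  v2 <- idx_of(min(o_end + 0.2 * period, duration))
  last_valley <- v1 - 1L + which.min(y0[v1:v2])
  data.frame(
    beat = seq_len(n_beats),
    onset_idx = vapply(onsets, idx_of, integer(1)),
    valley_idx = valley_idx,
    peak_idx = peak_idx,
    notch_idx = notch_idx,
    dia_peak_idx = dia_idx,
    next_valley_idx = c(valley_idx[-1], last_valley)
  )
}
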