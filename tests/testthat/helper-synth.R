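# Shared fixtures, all generated in code.

# A record with every stochastic component switched off: no white noise, no
# mains, no drift, no amplitude modulation.
clean_record <- function(hr = 88, duration = 30, fs = 500, seed = 1L,
                         beat = beat_model(), ptt = 0.25, notch_shift = 0) {
  spec <- subject_spec("t1", baseline_hr = hr, rng_seed = seed)
  preset <- phase_preset("before", hr_shift = 0, amp_modulation_depth = 0,
                         notch_shift = notch_shift, baseline_drift_amp = 0)
  ctrl <- synth_control(beat = beat, ptt = ptt, noise_sd = 0, mains_amp = 0)
  generate_record(spec, preset, duration = duration, fs = fs, control = ctrl)
}

# Pure tone as a signal object.
tone <- function(freq, fs = 500, duration = 20, amp = 1, kind = "PPG") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  pw_signal(amp * sin(2 * pi * freq * t), fs = fs, kind = kind)
}

# Amplitude of a sinusoid-like signal measured on its middle third, where
# zero-phase filtering transients have died out.
mid_amplitude <- function(sig) {
  y <- sig$samples
  n <- length(y)
  mid <- y[round(n / 3):round(2 * n / 3)]
  sqrt(2 * mean(mid^2))
}

# Small numeric cohort table with a known linear structure, for the dataset
# and reduction modules (no signal pipeline involved).
toy_cohort <- function(n = 84, p = 6, seed = 1L) {
  withr::with_seed(seed, {
    ptt <- runif(n, 0.18, 0.32)
    ai <- runif(n, 1.6, 3.1)
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    df <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      habit = sample(c("NC", "EC", "SH"), n, replace = TRUE),
      phase = "before",
      sbp_ref = -3.5 + 25 / ptt + 5 * ai,
      dbp_ref = 3.5 + 15 / ptt + 3 * ai,
      ptt_mean = ptt, ai_mean = ai
    )
    cbind(df, as.data.frame(X))
  })
}

quiet <- function(expr) suppressMessages(expr)
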