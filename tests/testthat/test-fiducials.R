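conditioned <- function(rec) {
  list(ppg = normalize_signal(notch_filter(bandpass(rec$ppg))),
       ecg = normalize_signal(notch_filter(bandpass(rec$ecg))))
}

test_that("peaks and feet recover the generator ground truth", {
  rec <- clean_record(hr = 88)
  sig <- conditioned(rec)
  b <- detect_peaks_valleys(sig$ppg)
  tr <- rec$truth$beats
  expect_equal(nrow(b), 44)
  expect_lte(median(abs(b$peak_idx - tr$peak_idx)), 2)
  expect_true(all(b$valley_idx < b$peak_idx))
  expect_true(all(b$peak_idx < b$next_valley_idx))
})

test_that("non-pulsatile inputs raise insufficient-signal errors", {
  ramp <- pw_signal(seq(0, 1, length.out = 2000), fs = 500)
  expect_error(detect_peaks_valleys(ramp), class = "pulsebp_insufficient_signal")
  expect_error(detect_r_peaks(pw_signal(rep(0.5, 2000), fs = 500, kind = "ECG")),
               class = "pulsebp_insufficient_signal")
})

test_that("notch detection matches ground truth and respects ordering", {
  rec <- clean_record(hr = 88)
  sig <- conditioned(rec)
  b <- detect_notch(sig$ppg, detect_peaks_valleys(sig$ppg))
  tr <- rec$truth$beats
  ok <- !is.na(b$notch_idx) & !is.na(tr$notch_idx)
  expect_gt(mean(ok), 0.9)
  expect_lte(median(abs(b$notch_idx[ok] - tr$notch_idx[ok])), 3)
  expect_true(all(b$peak_idx[ok] < b$notch_idx[ok]))
  expect_true(all(b$notch_idx[ok] < b$next_valley_idx[ok]))
})

test_that("a beat without a diastolic wave gets no fabricated notch", {
  rec <- clean_record(beat = beat_model(diastolic_amp = 1e-6), duration = 10)
  sig <- conditioned(rec)
  b <- detect_notch(sig$ppg, detect_peaks_valleys(sig$ppg))
  expect_true(all(is.na(b$notch_idx)))
})

test_that("shifting the diastolic wave moves the detected notch monotonically", {
  med_notch <- vapply(c(0, 0.03, 0.06), function(sh) {
    rec <- clean_record(hr = 75, duration = 15, notch_shift = sh)
    sig <- conditioned(rec)
    b <- detect_notch(sig$ppg, detect_peaks_valleys(sig$ppg))
    stats::median(b$notch_idx - b$peak_idx, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_notch) > 0))
})

test_that("both notch rules run; the derivative-peak rule lands later", {
  rec <- clean_record(hr = 80, duration = 15)
  sig <- conditioned(rec)
  base <- detect_peaks_valleys(sig$ppg)
  zc <- detect_notch(sig$ppg, base, method = "d1_zero")
  dp <- detect_notch(sig$ppg, base, method = "d1_peak")
  ok <- !is.na(zc$notch_idx) & !is.na(dp$notch_idx)
  expect_gt(mean(ok), 0.8)
  # the rising-edge maximum sits after the pulse minimum on smooth beats
  expect_gt(median(dp$notch_idx[ok] - zc$notch_idx[ok]), 0)
})

test_that("R-peak detection is exact on synthetic ECG", {
  rec <- clean_record(hr = 88)
  sig <- conditioned(rec)
  rp <- detect_r_peaks(sig$ecg)
  expect_length(rp$indices, 44)
  n <- min(length(rp$indices), length(rec$truth$r_idx))
  expect_lte(median(abs(rp$indices[1:n] - rec$truth$r_idx[1:n])), 2)
  expect_true(all(diff(rp$indices) > 0))
})

test_that("detection is translation-equivariant away from the edges", {
  rec <- clean_record(hr = 80, duration = 20)
  sig <- conditioned(rec)
  k <- 750L
  shifted <- pw_signal(sig$ppg$samples[(k + 1):length(sig$ppg$samples)],
                       fs = 500, kind = "PPG")
  p1 <- attr(detect_peaks_valleys(sig$ppg), "peaks")
  p2 <- attr(detect_peaks_valleys(shifted), "peaks")
  common <- intersect(p1 - k, p2)
  common <- common[common > 500 & common < length(shifted$samples) - 500]
  expect_gt(length(common), 10)
  expect_true(all((common + k) %in% p1))
})

test_that("outlier-beat rejection removes exactly the corrupted beat", {
  # amplitude-modulated record: the beat-amplitude spread is physiological,
  # so the MAD gate has a realistic scale
  rec <- generate_record(subject_spec("o1", baseline_hr = 80, rng_seed = 9L),
                         phase_presets("before")[[1]], duration = 20)
  sig <- conditioned(rec)
  b <- detect_peaks_valleys(sig$ppg)
  clean <- reject_outlier_beats(b, sig$ppg)
  expect_equal(nrow(clean$log), 0)
  # second pass removes nothing (idempotence)
  again <- reject_outlier_beats(clean$beats, sig$ppg)
  expect_equal(nrow(again$log), 0)

  # triple one beat's amplitude above its foot
  y <- sig$ppg$samples
  k <- 7
  span <- b$valley_idx[k]:b$next_valley_idx[k]
  y[span] <- y[b$valley_idx[k]] + 3 * (y[span] - y[b$valley_idx[k]])
  spiked <- pw_signal(y, fs = 500, kind = "PPG")
  b2 <- detect_peaks_valleys(spiked)
  res <- reject_outlier_beats(b2, spiked)
  expect_gte(nrow(res$log), 1)
  bad_peaks <- b2$peak_idx[res$log$beat]
  expect_true(all(abs(bad_peaks - b$peak_idx[k]) < 200))
  expect_error(reject_outlier_beats(b[1:2, ], sig$ppg),
               class = "pulsebp_insufficient_signal")
})

test_that("fiducials export to CSV with the documented columns", {
  rec <- clean_record(duration = 10)
  sig <- conditioned(rec)
  b <- detect_notch(sig$ppg, detect_peaks_valleys(sig$ppg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fiducials(b, path)
  back <- utils::read.csv(path)
  expect_named(back, c("beat", "valley_idx", "peak_idx", "notch_idx",
                       "next_valley_idx"))
  expect_equal(back$peak_idx, b$peak_idx)
})
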