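# brute-force oracles, deliberately naive
zcr_loop <- function(y, method = "sign_change", center = TRUE) {
  if (center) y <- y - mean(y)
  n <- length(y)
  if (method == "sign_change") {
    c <- 0
    for (i in 2:n) if (y[i] * y[i - 1] < 0) c <- c + 1
    c / (n - 1)
  } else {
    sum(vapply(y, function(v) v < 0, logical(1))) / n
  }
}

entropy_loop <- function(y) {
  e <- 0
  for (v in y) if (v^2 > 0) e <- e - v^2 * log(v^2)
  e
}

trapz_loop <- function(y, dt, baseline) {
  s <- 0
  for (i in 2:length(y)) {
    s <- s + dt * ((y[i] - baseline) + (y[i - 1] - baseline)) / 2
  }
  s
}

test_that("zero-crossing rate matches its definitions", {
  expect_equal(zero_crossing_rate(c(2, 3, 1, 5), center = FALSE), 0)
  expect_equal(zero_crossing_rate(c(2, 3, 1, 5), method = "literal",
                                  center = FALSE), 0)
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1), center = FALSE), 1)
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1), method = "literal",
                                  center = FALSE), 0.5)
  # k full periods of a centred sinusoid cross zero 2k times (phase offset
  # keeps samples off the exact zeros)
  k <- 7; n <- 1400
  s <- sin(2 * pi * k * (0:(n - 1)) / n + 0.37)
  expect_lt(abs(zero_crossing_rate(s, center = FALSE) - 2 * k / (n - 1)),
            2 / (n - 1))
})

test_that("Shannon entropy follows the 0 log 0 convention", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(numeric(8)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 0.25 * log(16))
  expect_warning(shannon_entropy(c(0.5, 1.2)), "outside")
})

test_that("zcr and entropy agree with loop oracles on random inputs", {
  withr::with_seed(10, {
    for (i in 1:25) {
      y <- rnorm(50 + i)
      expect_equal(zero_crossing_rate(y), zcr_loop(y), tolerance = 1e-12)
      expect_equal(zero_crossing_rate(y, "literal", center = FALSE),
                   zcr_loop(y, "literal", center = FALSE), tolerance = 1e-12)
      u <- y / max(abs(y))
      expect_equal(shannon_entropy(u), entropy_loop(u), tolerance = 1e-12)
    }
  })
})

test_that("beat features satisfy their defining identities", {
  rec <- clean_record(hr = 88)
  ppg <- normalize_signal(notch_filter(bandpass(rec$ppg)))
  ecg <- normalize_signal(notch_filter(bandpass(rec$ecg)))
  beats <- detect_notch(ppg, detect_peaks_valleys(ppg))
  rp <- detect_r_peaks(ecg)
  bf <- beat_features(ppg, beats, rp)

  ok <- stats::complete.cases(bf)
  expect_gt(sum(ok), 30)
  # PR = 60 / PPI, SI = sa / DT, AI = sa / Da, IPA = SA / DA
  expect_equal(bf$pulse_rate[ok], 60 / bf$ppi[ok], tolerance = 1e-12)
  expect_equal(bf$stiffness_index[ok], bf$sys_amp[ok] / bf$dia_time[ok],
               tolerance = 1e-12)
  expect_equal(bf$aug_index[ok], bf$sys_amp[ok] / bf$dia_amp[ok],
               tolerance = 1e-12)
  expect_equal(bf$ipa[ok], bf$sys_area[ok] / bf$dia_area[ok], tolerance = 1e-12)
  # ST + DT = PI to within one sample
  expect_lt(max(abs(bf$sys_time[ok] + bf$dia_time[ok] - bf$pulse_interval[ok])),
            1 / 500 + 1e-12)
  # a 60/88 s R-R interval reads back as 88 bpm
  expect_equal(median(bf$heart_rate, na.rm = TRUE), 88, tolerance = 0.01)
  expect_equal(median(bf$ptt_p, na.rm = TRUE), 0.25, tolerance = 0.01)
})

test_that("beat areas agree with a trapezoidal loop oracle", {
  rec <- clean_record(hr = 80, duration = 15)
  ppg <- normalize_signal(notch_filter(bandpass(rec$ppg)))
  beats <- detect_notch(ppg, detect_peaks_valleys(ppg))
  bf <- beat_features(ppg, beats, NULL)
  y <- ppg$samples
  for (k in which(!is.na(beats$notch_idx))[1:10]) {
    v <- beats$valley_idx[k]; nt <- beats$notch_idx[k]
    nv <- beats$next_valley_idx[k]
    expect_equal(bf$sys_area[k], trapz_loop(y[v:nt], 1 / 500, y[v]),
                 tolerance = 1e-9)
    expect_equal(bf$dia_area[k], trapz_loop(y[nt:nv], 1 / 500, y[v]),
                 tolerance = 1e-9)
  }
})

test_that("time rescaling scales durations and inverts rates", {
  rec <- clean_record(hr = 80, duration = 15)
  ppg <- normalize_signal(notch_filter(bandpass(rec$ppg)))
  beats <- detect_peaks_valleys(ppg)
  # same samples declared at half the sampling rate: every duration doubles
  slow <- pw_signal(ppg$samples, fs = 250, kind = "PPG")
  bf1 <- beat_features(ppg, beats, NULL)
  bf2 <- beat_features(slow, beats, NULL)
  ok <- !is.na(bf1$ppi)
  expect_equal(bf2$sys_time, 2 * bf1$sys_time, tolerance = 1e-12)
  expect_equal(bf2$pulse_interval, 2 * bf1$pulse_interval, tolerance = 1e-12)
  expect_equal(bf2$ppi[ok], 2 * bf1$ppi[ok], tolerance = 1e-12)
  expect_equal(bf2$pulse_rate[ok], bf1$pulse_rate[ok] / 2, tolerance = 1e-12)
  expect_equal(bf2$sys_amp, bf1$sys_amp, tolerance = 1e-12)
})

test_that("amplitude rescaling scales amplitudes and fixes the ratios", {
  rec <- clean_record(hr = 80, duration = 15)
  ppg <- notch_filter(bandpass(rec$ppg))
  beats <- detect_notch(ppg, detect_peaks_valleys(ppg))
  scaled <- pw_signal(3 * ppg$samples, fs = 500, kind = "PPG")
  bf1 <- beat_features(ppg, beats, NULL)
  bf3 <- beat_features(scaled, beats, NULL)
  ok <- stats::complete.cases(bf1[c("sys_amp", "dia_amp", "sys_area", "ipa")])
  expect_equal(bf3$sys_amp[ok], 3 * bf1$sys_amp[ok], tolerance = 1e-9)
  expect_equal(bf3$dia_amp[ok], 3 * bf1$dia_amp[ok], tolerance = 1e-9)
  expect_equal(bf3$sys_area[ok], 3 * bf1$sys_area[ok], tolerance = 1e-9)
  expect_equal(bf3$ipa[ok], bf1$ipa[ok], tolerance = 1e-9)
  expect_equal(bf3$aug_index[ok], bf1$aug_index[ok], tolerance = 1e-9)
})

test_that("skewness and kurtosis match the pinned e1071 conventions", {
  skip_if_not_installed("e1071")
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- rnorm(30 + i)
      expect_equal(skewness_adj(x), e1071::skewness(x, type = 2),
                   tolerance = 1e-12)
      expect_equal(kurtosis_pearson(x), e1071::kurtosis(x, type = 1) + 3,
                   tolerance = 1e-12)
    }
  })
  expect_equal(mean(c(1, 2, 3, 4, 5)), 3)
  expect_equal(sd_sample(c(1, 2, 3, 4, 5)), sqrt(2.5))
  expect_equal(skewness_adj(rep(4, 10)), 0)
  expect_equal(kurtosis_pearson(rep(4, 10)), 0)
})

test_that("the core preset emits exactly 65 uniquely named features", {
  nm_core <- feature_preset_names("core")
  nm_full <- feature_preset_names("full")
  expect_length(nm_core, 65)
  expect_length(nm_full, 75)
  expect_false(any(duplicated(nm_core)))
  expect_true(all(nm_core %in% nm_full))
  expect_error(feature_preset_names("nope"), class = "pulsebp_invalid_argument")
})

test_that("aggregation handles degenerate series and labels", {
  rec <- clean_record(hr = 88, duration = 10)
  ppg <- normalize_signal(notch_filter(bandpass(rec$ppg)))
  ecg <- normalize_signal(notch_filter(bandpass(rec$ecg)))
  bf <- data.frame(matrix(1, nrow = 5, ncol = 17))
  names(bf) <- pulsebp:::BEAT_SERIES
  expect_message(
    fv <- aggregate_features(bf, ppg, ecg, preset = "core",
                             habit = "NC", phase = "before"),
    "degenerate"
  )
  expect_equal(fv$sys_amp_mean, 1)
  expect_equal(fv$sys_amp_sd, 0)
  expect_equal(fv$sys_amp_kurt, 0)
  expect_equal(fv$habit, "NC")
  expect_error(aggregate_features(bf[1:2, ], ppg, ecg),
               class = "pulsebp_insufficient_signal")
})
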