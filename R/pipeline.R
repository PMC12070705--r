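#' Condition a record and extract its window feature vector
#'
#' The standard conditioning path for one 30-s window: band-pass (PPG
#' 0.05--30 Hz, ECG 0.05--140 Hz), 48--52 Hz mains notch, min-max
#' normalization, peak/valley detection, dicrotic-notch detection, R-peak
#' detection, MAD-based beat rejection, per-beat features, and statistical
#' aggregation into the registry preset's feature vector.
#'
#' @param record A `pw_record` from [generate_record()], or a list with
#'   `ppg` and `ecg` [pw_signal()]s.
#' @param preset Feature registry preset.
#' @param notch_method Notch rule passed to [detect_notch()].
#' @return A one-row feature data.frame (see [aggregate_features()]).
#' @export
extract_window_features <- function(record, preset = "core",
                                    notch_method = "d1_zero") {
  ppg <- normalize_signal(notch_filter(bandpass(record$ppg, ppg_filter_spec())))
  ecg <- normalize_signal(notch_filter(bandpass(record$ecg, ecg_filter_spec())))
  beats <- detect_peaks_valleys(ppg)
  beats <- detect_notch(ppg, beats, method = notch_method)
  rp <- detect_r_peaks(ecg)
  kept <- reject_outlier_beats(beats, ppg)
  bf <- beat_features(ppg, kept$beats, rp)
  aggregate_features(bf, ppg, ecg, preset = preset)
}

#' Run the cohort-level estimation pipeline
#'
#' Expansion, split, reduction and regression in the modelled order:
#' expand the feature table to `target_n` rows by rank-ordered cubic
#' interpolation, split 85/15, standardize + PCA to `k` components on the
#' training partition, and fit one GP per pressure target (Matern 5/2 for
#' SBP, exponential for DBP), optionally tuning each length-scale on the
#' 0.01--0.5 grid with fivefold CV. Test-set predictions are evaluated
#' against the held-out references.
#'
#' With `split_before_expand = TRUE` the measured rows are split first and
#' only the training partition is expanded (to `target_n * train_frac`
#' rows), so no interpolated row straddles the split — the statistically
#' safer mode; the default reproduces the historical expand-then-split
#' behaviour, whose interpolated neighbours leak across the split and
#' deflate test error.
#'
#' @param cohort Measured cohort table from [generate_cohort()].
#' @param target_n Expanded row count (default 870).
#' @param k Retained principal components (default 12).
#' @param sbp_kernel,dbp_kernel [kernel_config()]s used when `tune = FALSE`
#'   (defaults: Matern 5/2 with sigma 0.1367; exponential with sigma
#'   0.0807).
#' @param tune Tune each length-scale by CV instead of using the preset
#'   sigmas.
#' @param train_frac Training fraction.
#' @param split_before_expand See above.
#' @param train_phase Phase filter for fitting (default `"before"`).
#' @param rng_seed Seed for split, folds.
#' @return A list: `models` (per target), `kernels`, `eval` (per-target
#'   test metrics), `predictions` (test-set estimates with references),
#'   `reduction`, `split`.
#' @export
run_bp_pipeline <- function(cohort, target_n = 870, k = 12,
                            sbp_kernel = kernel_config("matern52", 0.1367),
                            dbp_kernel = kernel_config("exponential", 0.0807),
                            tune = FALSE, train_frac = 0.85,
                            split_before_expand = FALSE,
                            train_phase = "before", rng_seed = 1L) {
  if (!is.null(train_phase) && "phase" %in% names(cohort) &&
      !train_phase %in% cohort$phase) {
    stop_invalid(sprintf("cohort has no '%s' rows to train on", train_phase))
  }
  if (split_before_expand) {
    sp <- split_cohort(cohort, train_frac, rng_seed)
    n_train_target <- max(nrow(sp$train), round(target_n * train_frac))
    train_tbl <- expand_cohort(sp$train, n_train_target)
    test_tbl <- sp$test
  } else {
    expanded <- expand_cohort(cohort, target_n)
    sp <- split_cohort(expanded, train_frac, rng_seed)
    train_tbl <- sp$train
    test_tbl <- sp$test
  }
  red <- reduce_fit(train_tbl, "fixed_k", k = k)
  train_red <- reduce_transform(red, train_tbl)
  test_red <- reduce_transform(red, test_tbl)

  kernels <- list(SBP = sbp_kernel, DBP = dbp_kernel)
  models <- list()
  evals <- list()
  preds <- list()
  for (tg in c("SBP", "DBP")) {
    if (tune) {
      kernels[[tg]] <- gpr_tune_sigma(
        train_red, target = tg, family = kernels[[tg]]$family,
        noise_level = kernels[[tg]]$noise_level,
        rng_seed = rng_seed, train_phase = train_phase
      )
    }
    models[[tg]] <- gpr_fit(train_red, target = tg, kernel = kernels[[tg]],
                            train_phase = train_phase)
    pr <- predict(models[[tg]], test_red)
    ref <- if (tg == "SBP") test_red$sbp_ref else test_red$dbp_ref
    evals[[tg]] <- evaluate_bp(pr$estimate, ref)
    preds[[tg]] <- data.frame(target = tg, estimate = pr$estimate,
                              sd = pr$sd, reference = ref)
  }
  list(models = models, kernels = kernels, eval = evals,
       predictions = do.call(rbind, preds), reduction = red, split = sp)
}
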