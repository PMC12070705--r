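#' Zero-crossing rate
#'
#' Two semantics are available. The default, `"sign_change"`, is the rate of
#' sign changes: `count(y[n] * y[n-1] < 0) / (N - 1)`. The `"literal"` form
#' instead counts the fraction of negative samples, `count(y[n] < 0) / N`.
#' Because a \[0, 1\]-normalized trace never changes sign, the rate is
#' computed about the signal mean by default (`center = TRUE`).
#'
#' @param y Numeric vector or [pw_signal()].
#' @param method `"sign_change"` (default) or `"literal"`.
#' @param center Subtract the mean before counting (default TRUE).
#' @return A rate in \[0, 1\].
#' @examples
#' zero_crossing_rate(c(1, -1, 1, -1), center = FALSE) # 1
#' zero_crossing_rate(c(1, -1, 1, -1), method = "literal", center = FALSE) # 0.5
#' @export
zero_crossing_rate <- function(y, method = c("sign_change", "literal"),
                               center = TRUE) {
  method <- match.arg(method)
  if (inherits(y, "pw_signal")) y <- y$samples
  n <- length(y)
  if (n < 2) stop_invalid("need at least 2 samples")
  if (center) y <- y - mean(y)
  if (method == "sign_change") {
    sum(y[-1] * y[-n] < 0) / (n - 1)
  } else {
    sum(y < 0) / n
  }
}

#' Shannon energy entropy
#'
#' `E = -sum(y^2 * ln(y^2))` with the convention `0 * ln 0 = 0`. Samples are
#' expected in \[-1, 1\] (the pipeline normalizes the PPG to \[0, 1\] and
#' scales derivative channels to unit maximum); values outside that range
#' make the summand sign uninterpretable and trigger a warning.
#'
#' @param y Numeric vector or [pw_signal()].
#' @return The entropy value (dimensionless).
#' @examples
#' shannon_entropy(c(1, 0, 0, 0)) # 0
#' shannon_entropy(c(0.5, 0.5))   # 0.25 * log(16)
#' @export
shannon_entropy <- function(y) {
  if (inherits(y, "pw_signal")) y <- y$samples
  if (any(abs(y) > 1)) {
    warning("samples outside [-1, 1]; Shannon entropy terms change sign")
  }
  y2 <- y^2
  terms <- ifelse(y2 > 0, y2 * log(y2), 0)
  -sum(terms)
}

# Names of the per-beat series, in registry order. The first 14 are the
# classical PPG morphology set; heart_rate and the two transit times come
# from the paired ECG.
BEAT_SERIES <- c("sys_amp", "dia_amp", "sys_area", "dia_area", "ipa",
                 "sys_time", "dia_time", "pulse_interval", "stiffness_index",
                 "ppi", "pulse_rate", "fwhm", "sa_dt_ratio", "aug_index",
                 "heart_rate", "ptt_f", "ptt_p")

# Full width at half maximum of the systolic wave, with sub-sample linear
# interpolation at both half-height crossings. Returns NA if a crossing is
# missing inside the beat.
beat_fwhm <- function(y, v, p, nv, fs) {
  half <- y[v] + (y[p] - y[v]) / 2
  left <- NA_real_
  for (i in seq(p, v + 1)) {
    if (y[i - 1] < half && y[i] >= half) {
      left <- (i - 1) + (half - y[i - 1]) / (y[i] - y[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(p, nv - 1)) {
    if (y[i] >= half && y[i + 1] < half) {
      right <- i + (y[i] - half) / (y[i] - y[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / fs
}

#' Per-beat morphological features
#'
#' Computes, for every beat with complete fiducials, the morphology set:
#' systolic amplitude `sys_amp` (peak minus foot), diastolic amplitude
#' `dia_amp` (diastolic-wave peak after the notch, minus foot), systolic and
#' diastolic areas (trapezoidal area above the foot level, foot to notch and
#' notch to next foot), inflection-point area ratio `ipa = SA/DA`, systolic
#' and diastolic times, pulse interval, stiffness index `sys_amp/dia_time`,
#' peak-to-peak interval and pulse rate `60/PPI`, full width at half
#' maximum, the systolic-amplitude/diastolic-time ratio, augmentation index
#' `sys_amp/dia_amp`, per-beat heart rate `60/T_RR` from the enclosing
#' R-R interval, and the two transit times `ptt_f` (R-peak to foot) and
#' `ptt_p` (R-peak to systolic peak).
#'
#' Beats without a detected notch get NA for the notch-dependent features
#' (`dia_amp`, areas, `ipa`, `aug_index`); they are excluded per-series at
#' aggregation, never fabricated.
#'
#' @param ppg Conditioned PPG [pw_signal()].
#' @param beats Beat data.frame from [detect_notch()].
#' @param rpeaks An `r_peaks` object from [detect_r_peaks()] on the paired
#'   ECG, or NULL (ECG-linked features become NA).
#' @return A data.frame with one row per beat and the columns listed above.
#' @export
beat_features <- function(ppg, beats, rpeaks = NULL) {
  y <- ppg$samples
  fs <- ppg$fs
  nb <- nrow(beats)
  r <- if (is.null(rpeaks)) integer(0) else rpeaks$indices
  out <- data.frame(matrix(NA_real_, nrow = nb, ncol = length(BEAT_SERIES)))
  names(out) <- BEAT_SERIES
  dt <- 1 / fs
  for (k in seq_len(nb)) {
    v <- beats$valley_idx[k]; p <- beats$peak_idx[k]
    nv <- beats$next_valley_idx[k]; nt <- beats$notch_idx[k]
    foot <- y[v]
    sa <- y[p] - foot
    st <- (p - v) / fs
    dtime <- (nv - p) / fs
    out$sys_amp[k] <- sa
    out$sys_time[k] <- st
    out$dia_time[k] <- dtime
    out$pulse_interval[k] <- (nv - v) / fs
    out$stiffness_index[k] <- sa / dtime
    out$sa_dt_ratio[k] <- sa / dtime
    out$fwhm[k] <- beat_fwhm(y, v, p, nv, fs)
    if (!is.na(nt)) {
      dp_win <- y[nt:nv]
      dp_rel <- which.max(dp_win)
      if (dp_rel > 1 && dp_rel < length(dp_win)) {
        out$dia_amp[k] <- dp_win[dp_rel] - foot
        out$aug_index[k] <- sa / out$dia_amp[k]
      }
      sa_area <- trapezoid_area(y[v:nt], dt, baseline = foot)
      da_area <- trapezoid_area(y[nt:nv], dt, baseline = foot)
      out$sys_area[k] <- sa_area
      out$dia_area[k] <- da_area
      out$ipa[k] <- if (da_area != 0) sa_area / da_area else NA_real_
    }
    if (k < nb) {
      out$ppi[k] <- (beats$peak_idx[k + 1] - p) / fs
      out$pulse_rate[k] <- 60 / out$ppi[k]
    }
    if (length(r) >= 2) {
      j <- findInterval(p, r)
      if (j >= 1 && j < length(r)) {
        out$heart_rate[k] <- 60 / ((r[j + 1] - r[j]) / fs)
      }
      if (j >= 1) {
        ptt_p <- (p - r[j]) / fs
        if (ptt_p > 0 && ptt_p < 0.6) out$ptt_p[k] <- ptt_p
        # foot delay measured against the same R-peak that pairs with the
        # systolic peak; at slow heart rates the upstroke can start before
        # the R-peak, so a small negative delay is legitimate
        ptt_f <- (v - r[j]) / fs
        if (abs(ptt_f) < 0.6) out$ptt_f[k] <- ptt_f
      }
    }
  }
  out
}

# Feature registry cache (read once per session from the YAML shipped in
# inst/extdata).
.registry_env <- new.env(parent = emptyenv())

#' Feature registry presets
#'
#' The registry is configuration, not code: `feature_presets.yaml` under the
#' package's `extdata` lists, per preset, the per-beat series to aggregate,
#' the statistics applied to each, and the window-scalar features. The
#' `"core"` preset spans exactly 65 features (4 statistics over the 14
#' morphology series plus heart rate, 4 zero-crossing rates, and the PPG
#' Shannon entropy); the `"full"` preset adds the transit-time statistics
#' and the derivative entropies (75 features).
#'
#' @param preset Preset name.
#' @return For `feature_registry()`, the parsed registry list; for
#'   `feature_preset_names()`, the character vector of feature (column)
#'   names the preset emits, in order.
#' @export
feature_registry <- function() {
  if (is.null(.registry_env$registry)) {
    path <- system.file("extdata", "feature_presets.yaml", package = "pulsebp")
    if (path == "") stop_schema("feature_presets.yaml not found in package")
    .registry_env$registry <- yaml::read_yaml(path)
  }
  .registry_env$registry
}

#' @rdname feature_registry
#' @export
feature_preset_names <- function(preset = "core") {
  reg <- feature_registry()$presets[[preset]]
  if (is.null(reg)) stop_invalid(sprintf("unknown feature preset '%s'", preset))
  stat_names <- as.vector(t(outer(reg$beat_series, reg$stats, paste, sep = "_")))
  c(stat_names, reg$scalars)
}

#' Aggregate per-beat features into the window feature vector
#'
#' Each per-beat series is summarised by four statistics — mean, sample
#' standard deviation, adjusted skewness and Pearson (non-excess) kurtosis —
#' over its non-missing beats. Window scalars (zero-crossing rates of the
#' PPG, its first two derivatives, and the ECG; Shannon entropies of the PPG
#' and, in the full preset, its derivatives) are appended. Degenerate series
#' (zero variance) report skewness/kurtosis of 0, with a message.
#'
#' @param bf Per-beat feature data.frame from [beat_features()].
#' @param ppg,ecg Conditioned, normalized signals the window was measured
#'   on (used for the scalar features).
#' @param preset Registry preset name (`"core"` = 65 features).
#' @param habit,phase Optional labels attached to the output row.
#' @return A one-row data.frame with one column per registry feature (plus
#'   `habit`/`phase` when given).
#' @export
aggregate_features <- function(bf, ppg, ecg, preset = "core",
                               habit = NULL, phase = NULL) {
  if (nrow(bf) < 3) stop_insufficient("need at least 3 beats to aggregate")
  reg <- feature_registry()$presets[[preset]]
  if (is.null(reg)) stop_invalid(sprintf("unknown feature preset '%s'", preset))

  stats_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(c(mean = NA_real_, sd = NA_real_, skew = NA_real_, kurt = NA_real_))
    }
    s <- sd_sample(x)
    if (length(x) < 2 || is.na(s)) s <- 0
    if (s == 0) {
      message("degenerate series (zero variance): skewness/kurtosis set to 0")
      return(c(mean = mean(x), sd = 0, skew = 0, kurt = 0))
    }
    c(mean = mean(x), sd = s, skew = skewness_adj(x), kurt = kurtosis_pearson(x))
  }

  vals <- list()
  for (series in reg$beat_series) {
    st <- stats_of(bf[[series]])[reg$stats]
    names(st) <- paste(series, reg$stats, sep = "_")
    vals <- c(vals, as.list(st))
  }

  d1 <- signal_derivative(ppg)
  d2 <- signal_derivative(d1)
  unit_scale <- function(v) {
    m <- max(abs(v))
    if (m > 0) v / m else v
  }
  scalar_pool <- list(
    zcr_ppg = function() zero_crossing_rate(ppg),
    zcr_ppg_d1 = function() zero_crossing_rate(d1),
    zcr_ppg_d2 = function() zero_crossing_rate(d2),
    zcr_ecg = function() zero_crossing_rate(ecg),
    entropy_ppg = function() shannon_entropy(ppg$samples),
    entropy_ppg_d1 = function() shannon_entropy(unit_scale(d1$samples)),
    entropy_ppg_d2 = function() shannon_entropy(unit_scale(d2$samples))
  )
  for (sc in reg$scalars) {
    f <- scalar_pool[[sc]]
    if (is.null(f)) stop_schema(sprintf("unknown scalar feature '%s'", sc))
    vals[[sc]] <- f()
  }

  out <- as.data.frame(vals)
  if (any(!vapply(out, is.finite, logical(1)))) {
    stop_degenerate("non-finite value in aggregated feature vector")
  }
  if (!is.null(habit)) out$habit <- habit
  if (!is.null(phase)) out$phase <- phase
  out
}
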