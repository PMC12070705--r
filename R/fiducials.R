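# Prominence-based local-extremum picker. A candidate peak's prominence is
# the height above the higher of the two deepest valleys separating it from
# higher terrain (or the record edge). Peaks closer than `min_dist` samples
# are thinned, keeping the higher one.
find_peaks <- function(y, min_dist, min_prom) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(cand) == 0) return(integer(0))
  # distance-thin first (greedy, highest candidate wins), so the O(n)
  # prominence pass only runs for the surviving handful of peaks
  cand <- cand[order(y[cand], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in cand) {
    if (length(chosen) == 0 || all(abs(i - chosen) >= min_dist)) {
      chosen <- c(chosen, i)
    }
  }
  chosen <- sort(chosen)
  prom <- vapply(chosen, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    higher_l <- which(left >= h)
    lo_l <- if (length(higher_l) == 0) min(left) else min(left[max(higher_l):(i - 1)])
    right <- y[(i + 1):n]
    higher_r <- which(right >= h)
    lo_r <- if (length(higher_r) == 0) min(right) else min(right[seq_len(min(higher_r))])
    h - max(lo_l, lo_r)
  }, numeric(1))
  chosen[prom >= min_prom]
}

# Dominant beat period in samples, from the autocorrelation maximum over
# physiological lags (0.25 s -- 2 s). Returns NA when no positive
# autocorrelation peak exists in that band.
dominant_period <- function(y, fs) {
  lo <- max(2L, as.integer(round(0.25 * fs)))
  hi <- min(length(y) - 2L, as.integer(round(2 * fs)))
  if (hi <= lo) return(NA_integer_)
  ac <- stats::acf(y - mean(y), lag.max = hi, plot = FALSE,
                   demean = FALSE)$acf[-1]
  band <- lo:hi
  best <- band[which.max(ac[band])]
  if (ac[best] <= 0) NA_integer_ else best
}

#' Detect PPG systolic peaks and pulse feet
#'
#' Systolic peaks are prominence-filtered local maxima (prominence at least
#' `min_prominence` of the signal range) with an adaptive refractory
#' distance: 70 % of the dominant beat period estimated from the signal's
#' autocorrelation (falling back to `min_dist_s` when no periodicity is
#' found). The adaptive distance suppresses diastolic waves, which sit
#' 35--65 % of a period away from the neighbouring systolic peaks, while
#' the fixed 0.25 s floor alone would not at low heart rates. The foot
#' (valley) of each beat is the minimum between consecutive peaks; exactly
#' one peak lies between consecutive valleys.
#'
#' @param ppg A conditioned, normalized PPG [pw_signal()].
#' @param min_dist_s Minimum peak separation floor in seconds.
#' @param min_prominence Prominence threshold as a fraction of signal range.
#' @return A data.frame of beat fiducials: `beat`, `valley_idx`, `peak_idx`,
#'   `notch_idx` (NA until [detect_notch()]), `next_valley_idx`, with the
#'   full peak index vector in attribute `peaks`.
#' @export
detect_peaks_valleys <- function(ppg, min_dist_s = 0.25, min_prominence = 0.25) {
  y <- ppg$samples
  rng <- diff(range(y))
  if (rng <= 0) stop_insufficient("signal is constant")
  period <- dominant_period(y, ppg$fs)
  min_dist <- max(round(min_dist_s * ppg$fs),
                  if (is.na(period)) 0L else round(0.7 * period))
  peaks <- find_peaks(y, min_dist = min_dist, min_prom = min_prominence * rng)
  if (length(peaks) < 2) {
    stop_insufficient("fewer than 2 pulses detected")
  }
  # feet: minimum between consecutive peaks, plus the lead-in and lead-out
  inner_feet <- vapply(seq_len(length(peaks) - 1), function(k) {
    a <- peaks[k]; b <- peaks[k + 1]
    a + which.min(y[(a + 1):(b - 1)])
  }, integer(1))
  med_ppi <- stats::median(diff(peaks))
  lead_in <- max(1L, peaks[1] - as.integer(round(0.8 * med_ppi)))
  first_foot <- lead_in - 1L + which.min(y[lead_in:(peaks[1] - 1L)])
  lead_out <- min(length(y), peaks[length(peaks)] + as.integer(round(0.8 * med_ppi)))
  last_foot <- peaks[length(peaks)] + which.min(y[(peaks[length(peaks)] + 1L):lead_out])
  feet <- c(first_foot, inner_feet, last_foot)
  beats <- data.frame(
    beat = seq_along(peaks),
    valley_idx = feet[-length(feet)],
    peak_idx = peaks,
    notch_idx = NA_integer_,
    next_valley_idx = feet[-1]
  )
  attr(beats, "peaks") <- peaks
  beats
}

#' Detect the dicrotic notch of each beat from the first derivative
#'
#' The first derivative is computed by central differences. Two rules are
#' available for each beat's search window (strictly between the systolic
#' peak and the next foot):
#'
#' * `"d1_zero"` (default): the first rising zero-crossing of the
#'   derivative, i.e. the local minimum of the pulse between the systolic
#'   and diastolic waves. This is unbiased on smooth pulses.
#' * `"d1_peak"`: the local maximum of the derivative in the window (the
#'   diastolic rising edge). On smooth pulses this lands systematically
#'   after the notch, by roughly half the diastolic rise time; it is kept as
#'   an alternative because some detection practice identifies the notch
#'   this way on sharp-incisura waveforms.
#'
#' Beats with no qualifying extremum keep `notch_idx = NA`; an absent notch
#' is represented, never fabricated.
#'
#' @param ppg The conditioned PPG [pw_signal()] the beats were detected on.
#' @param beats Beat data.frame from [detect_peaks_valleys()].
#' @param method Notch rule, `"d1_zero"` or `"d1_peak"`.
#' @return The beat data.frame with `notch_idx` filled where detectable.
#' @export
detect_notch <- function(ppg, beats, method = c("d1_zero", "d1_peak")) {
  method <- match.arg(method)
  d1 <- signal_derivative(ppg)$samples
  y <- ppg$samples
  for (k in seq_len(nrow(beats))) {
    a <- beats$peak_idx[k]
    b <- beats$next_valley_idx[k]
    if (b - a < 4) next
    win <- (a + 1):(b - 1)
    seg <- d1[win]
    idx <- NA_integer_
    if (method == "d1_zero") {
      cross <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)
      if (length(cross) > 0) {
        i <- cross[1]
        # a rising crossing only counts as a notch if the pulse rebounds
        rest <- y[win[i]:b]
        if (max(rest) - rest[1] > 1e-4 * diff(range(y))) idx <- win[i]
      }
    } else {
      # local maxima of d1 strictly inside the window
      lm <- which(diff(sign(diff(seg))) < 0) + 1L
      lm <- lm[seg[lm] > 0] # only genuine rising edges
      if (length(lm) > 0) idx <- win[lm[which.max(seg[lm])]]
    }
    beats$notch_idx[k] <- idx
  }
  beats
}

#' Detect ECG R-peaks
#'
#' Prominence-based peak picking on the conditioned ECG with a 0.25 s
#' refractory distance; detected trains whose inter-peak intervals fall
#' outside \[0.25 s, 2 s\] after median-based outlier rejection are trimmed.
#'
#' @param ecg A conditioned ECG [pw_signal()].
#' @param min_prominence Prominence threshold as a fraction of signal range.
#' @return A list of class `r_peaks` with `indices` (strictly increasing
#'   sample indices) and `fs`.
#' @export
detect_r_peaks <- function(ecg, min_prominence = 0.4) {
  y <- ecg$samples
  rng <- diff(range(y))
  if (rng <= 0) stop_insufficient("ECG signal is constant")
  idx <- find_peaks(y, min_dist = round(0.25 * ecg$fs),
                    min_prom = min_prominence * rng)
  if (length(idx) >= 3) {
    iv <- diff(idx) / ecg$fs
    ok <- iv >= 0.25 & iv <= 2
    # drop peaks that open an implausible interval (keep the earlier peak)
    idx <- idx[c(TRUE, ok)]
  }
  if (length(idx) < 2) stop_insufficient("fewer than 2 R-peaks detected")
  structure(list(indices = idx, fs = ecg$fs), class = "r_peaks")
}

#' Reject outlier beats
#'
#' A beat is discarded when its peak-to-peak interval or its systolic
#' amplitude (peak minus foot) falls outside median +/- 3 MAD of the record
#' (MAD with the usual 1.4826 consistency constant). This automated gate
#' replaces manual verification; every removal is logged with its reason.
#'
#' @param beats Beat data.frame from [detect_peaks_valleys()] /
#'   [detect_notch()].
#' @param ppg The PPG [pw_signal()] the beats belong to.
#' @param n_mad Rejection threshold in MADs.
#' @return A list with `beats` (surviving rows) and `log` (data.frame of
#'   `beat`, `reason` for each removal).
#' @export
reject_outlier_beats <- function(beats, ppg, n_mad = 3) {
  if (nrow(beats) < 3) stop_insufficient("need at least 3 beats")
  y <- ppg$samples
  amp <- y[beats$peak_idx] - y[beats$valley_idx]
  ppi <- c(diff(beats$peak_idx), NA) / ppg$fs
  flag_out <- function(x) {
    med <- stats::median(x, na.rm = TRUE)
    m <- stats::mad(x, na.rm = TRUE)
    if (!is.finite(m) || m == 0) return(rep(FALSE, length(x)))
    abs(x - med) > n_mad * m & !is.na(x)
  }
  bad_amp <- flag_out(amp)
  bad_ppi <- flag_out(ppi)
  reasons <- character(0)
  bad <- bad_amp | bad_ppi
  log <- data.frame(
    beat = beats$beat[bad],
    reason = ifelse(bad_amp[bad] & bad_ppi[bad], "amplitude+interval",
                    ifelse(bad_amp[bad], "amplitude", "interval"))
  )
  kept <- beats[!bad, , drop = FALSE]
  if (nrow(kept) == 0) stop_empty("all beats rejected as outliers")
  list(beats = kept, log = log)
}

#' Export beat fiducials as CSV
#'
#' @param beats Beat data.frame.
#' @param path File path.
#' @export
write_fiducials <- function(beats, path) {
  utils::write.csv(
    beats[c("beat", "valley_idx", "peak_idx", "notch_idx", "next_valley_idx")],
    path, row.names = FALSE
  )
  invisible(path)
}
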