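clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-subject random seed from a root seed
#'
#' One root seed drives a whole cohort; each subject receives a deterministic
#' seed `(root * 1000003 + index * 7919) mod (2^31 - 1)` so that records are
#' reproducible individually and insertion/removal of subjects does not
#' reshuffle the others.
#'
#' @param root_seed Integer root seed for the cohort.
#' @param index 1-based subject (or record) index.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(root_seed, index) {
  s <- (as.double(root_seed) * 1000003 + as.double(index) * 7919) %% 2147483629
  as.integer(s) + 1L
}

# Trapezoidal area of y (minus a baseline) over uniformly spaced samples.
# dt is the sample period in seconds; returns a.u. * s.
trapezoid_area <- function(y, dt, baseline = 0) {
  z <- y - baseline
  n <- length(z)
  if (n < 2) return(0)
  dt * sum((z[-1] + z[-n]) / 2)
}

# Sample standard deviation (n - 1 denominator), NA-safe.
sd_sample <- function(x) stats::sd(x, na.rm = TRUE)

#' Adjusted sample skewness
#'
#' Adjusted Fisher-Pearson estimator, `g1 * sqrt(n (n-1)) / (n - 2)`.
#' Degenerate series (zero variance or n < 3) return 0, matching the pinned
#' aggregation convention.
#'
#' @param x Numeric vector; NAs are dropped.
#' @return Skewness estimate (dimensionless).
#' @export
skewness_adj <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Pearson (non-excess) sample kurtosis
#'
#' `m4 / m2^2` with moments about the mean; a normal sample gives ~3.
#' Degenerate series return 0 (see [aggregate_features()]).
#'
#' @param x Numeric vector; NAs are dropped.
#' @return Kurtosis estimate (dimensionless).
#' @export
kurtosis_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2
}

#' Convert a pulse count in a window to beats per minute
#'
#' @param n_pulses Number of detected pulses in the window.
#' @param duration_s Window duration in seconds.
#' @return Pulse rate in beats per minute.
#' @examples
#' pulses_to_bpm(44, 30) # 88
#' pulses_to_bpm(50, 30) # 100
#' @export
pulses_to_bpm <- function(n_pulses, duration_s) {
  if (duration_s <= 0) stop_invalid("`duration_s` must be positive")
  60 * n_pulses / duration_s
}

# Column names that are labels/references, never features.
LABEL_COLS <- c("subject_id", "habit", "phase", "provenance", "sbp_ref", "dbp_ref")

feature_matrix <- function(table, exclude = LABEL_COLS) {
  cols <- setdiff(names(table), exclude)
  bad <- cols[!vapply(table[cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop_schema(paste0("non-numeric feature column(s): ", paste(bad, collapse = ", ")))
  }
  as.matrix(table[cols])
}
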