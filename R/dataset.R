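#' Expand a cohort table by rank-ordered cubic interpolation
#'
#' The table is sorted by reference DBP (ties broken by `subject_id`), each
#' numeric column is interpolated independently with a cubic spline over the
#' row rank `1..n`, and the splines are evaluated on `target_n` evenly spaced
#' ranks. Original rows are reproduced exactly wherever an evaluation rank
#' coincides with an original rank and keep their `"measured"` provenance;
#' all other rows are flagged `"interpolated"`. Label columns are copied
#' from the nearest original rank.
#'
#' Interpolated rows are not independent samples: neighbouring rows share
#' information, so a train/test split taken after expansion leaks across the
#' boundary. This is the historical behaviour of the modelled analysis;
#' [split_cohort()] on the measured rows first is the statistically safer
#' alternative (see [run_bp_pipeline()]'s `split_before_expand`).
#'
#' Columns where the spline overshoots the observed min/max envelope by more
#' than 5 % of the column range are reported in the `overshoot` attribute.
#'
#' @param table A cohort table (see [generate_cohort()]).
#' @param target_n Output row count (default 870; must be >= `nrow(table)`).
#' @return The expanded cohort table with a `provenance` column.
#' @export
expand_cohort <- function(table, target_n = 870) {
  n <- nrow(table)
  if (target_n < n) stop_invalid("`target_n` must be >= current row count")
  if (!all(c("dbp_ref") %in% names(table))) {
    stop_schema("cohort table needs a dbp_ref column")
  }
  ord <- order(table$dbp_ref, table$subject_id)
  table <- table[ord, , drop = FALSE]
  rownames(table) <- NULL
  if (target_n == n) {
    table$provenance <- "measured"
    return(table)
  }
  num_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      LABEL_COLS)
  lab_cols <- setdiff(names(table), num_cols)
  bad <- setdiff(lab_cols, LABEL_COLS)
  if (length(bad) > 0) {
    stop_schema(paste0("non-numeric feature column(s): ",
                       paste(bad, collapse = ", ")))
  }
  ranks <- seq_len(n)
  grid <- seq(1, n, length.out = target_n)
  on_knot <- abs(grid - round(grid)) < 1e-9
  nearest <- clamp(round(grid), 1, n)

  out <- data.frame(row.names = seq_len(target_n))
  overshoot <- character(0)
  for (cn in names(table)) {
    if (cn %in% num_cols || cn %in% c("sbp_ref", "dbp_ref")) {
      yi <- stats::spline(ranks, table[[cn]], xout = grid, method = "fmm")$y
      yi[on_knot] <- table[[cn]][nearest[on_knot]] # knots reproduce exactly
      rng <- range(table[[cn]])
      tol <- 0.05 * diff(rng)
      if (any(yi < rng[1] - tol | yi > rng[2] + tol)) {
        overshoot <- c(overshoot, cn)
      }
      out[[cn]] <- yi
    } else if (cn == "provenance") {
      next
    } else {
      out[[cn]] <- table[[cn]][nearest]
    }
  }
  out$provenance <- ifelse(on_knot, "measured", "interpolated")
  cols <- names(table)
  if (!"provenance" %in% cols) cols <- c(cols, "provenance")
  out <- out[cols]
  attr(out, "overshoot") <- overshoot
  out
}

#' Remove outlier rows from a cohort table
#'
#' A row is removed when any feature column lies outside median +/- 3 MAD of
#' that column (MAD with the 1.4826 consistency constant). Removing more
#' than half the table signals an upstream failure and raises an error.
#'
#' @param table A cohort table with at least 10 rows.
#' @param n_mad Threshold in MADs.
#' @return A list with `table` (surviving rows) and `log` (data.frame of row
#'   index, offending column, value).
#' @export
remove_outlier_rows <- function(table, n_mad = 3) {
  if (nrow(table) < 10) stop_invalid("need at least 10 rows")
  X <- feature_matrix(table)
  bad <- matrix(FALSE, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    med <- stats::median(X[, j])
    m <- stats::mad(X[, j])
    if (m > 0) bad[, j] <- abs(X[, j] - med) > n_mad * m
  }
  drop_row <- rowSums(bad) > 0
  if (mean(drop_row) > 0.5) {
    stop_pulsebp("more than 50% of rows flagged as outliers; upstream failure",
                 "pulsebp_outlier_flood")
  }
  log <- do.call(rbind, lapply(which(drop_row), function(i) {
    js <- which(bad[i, ])
    data.frame(row = i, column = colnames(X)[js], value = X[i, js])
  }))
  if (is.null(log)) log <- data.frame(row = integer(0), column = character(0),
                                      value = numeric(0))
  list(table = table[!drop_row, , drop = FALSE], log = log)
}

#' Seeded train/test split
#'
#' Disjoint, exhaustive split after a seeded shuffle. The test-set size is
#' `round-half-up(n * (1 - train_frac))`, the training set takes the
#' remainder: 870 rows at 85 % training give 739 train + 131 test.
#'
#' @param table A cohort table.
#' @param train_frac Training fraction in (0, 1).
#' @param rng_seed Integer seed for the shuffle.
#' @return A list with `train` and `test` tables and integer row indices
#'   `train_idx` / `test_idx` (a split manifest for exact reruns).
#' @export
split_cohort <- function(table, train_frac = 0.85, rng_seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop_invalid("need at least 2 rows to split")
  if (train_frac <= 0 || train_frac >= 1) {
    stop_invalid("`train_frac` must be in (0, 1)")
  }
  n_test <- floor(n * (1 - train_frac) + 0.5)
  if (n_test == 0 || n_test == n) {
    stop_invalid("split would leave an empty partition")
  }
  perm <- withr::with_seed(rng_seed, sample.int(n))
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[(n_test + 1):n])
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Save a split manifest as JSON
#'
#' @param split Result of [split_cohort()].
#' @param path File path.
#' @export
write_split_manifest <- function(split, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_invalid("jsonlite is required to write split manifests")
  }
  jsonlite::write_json(list(train_idx = split$train_idx,
                            test_idx = split$test_idx),
                       path, auto_unbox = FALSE)
  invisible(path)
}
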