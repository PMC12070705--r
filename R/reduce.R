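#' Fit a standardize-then-PCA reduction model
#'
#' Feature columns are standardized to zero mean and unit variance with
#' training statistics (the features have heterogeneous units, so
#' standardization before decomposition is required), constant columns are
#' dropped with a message, and principal components are extracted with a
#' pinned sign convention (the largest-magnitude loading of each component
#' is positive), making the decomposition deterministic.
#'
#' @param table Cohort table (training partition).
#' @param selection_mode `"fixed_k"` (default, `k` components) or
#'   `"variance_threshold"` (smallest k whose cumulative explained-variance
#'   ratio reaches `threshold`).
#' @param k Number of components for `fixed_k` (default 12).
#' @param threshold Cumulative variance fraction for `variance_threshold`.
#' @return A `bp_reduction` model: centers, scales, loadings,
#'   explained-variance ratios, selected_k.
#' @export
reduce_fit <- function(table, selection_mode = c("fixed_k", "variance_threshold"),
                       k = 12, threshold = 0.95) {
  selection_mode <- match.arg(selection_mode)
  X <- feature_matrix(table)
  if (nrow(X) < k + 1) stop_invalid("need at least k + 1 rows to fit")
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  keep <- scales > 1e-12
  if (any(!keep)) {
    message("dropping constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  centers <- centers[keep]
  scales <- scales[keep]
  Xs <- sweep(sweep(X, 2, centers), 2, scales, "/")
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  rot <- pr$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  ratios <- pr$sdev^2 / sum(pr$sdev^2)
  model <- structure(
    list(features = colnames(X), centers = centers, scales = scales,
         rotation = rot, sdev = pr$sdev, ratios = ratios,
         selection_mode = selection_mode, threshold = threshold,
         selected_k = NA_integer_),
    class = "bp_reduction"
  )
  reduce_select(model, selection_mode,
                if (selection_mode == "fixed_k") k else threshold)
}

#' Choose the retained dimensionality of a reduction model
#'
#' @param model A `bp_reduction` model.
#' @param mode `"fixed_k"` or `"variance_threshold"`.
#' @param k_or_threshold Component count, or cumulative-variance fraction.
#' @return The model with `selected_k` set.
#' @export
reduce_select <- function(model, mode = c("fixed_k", "variance_threshold"),
                          k_or_threshold = 12) {
  mode <- match.arg(mode)
  p <- length(model$ratios)
  if (mode == "fixed_k") {
    k <- as.integer(k_or_threshold)
    if (k < 1 || k > p) stop_invalid("k must lie in [1, n_features]")
  } else {
    if (k_or_threshold <= 0 || k_or_threshold > 1) {
      stop_invalid("threshold must lie in (0, 1]")
    }
    cum <- cumsum(model$ratios)
    k <- which(cum >= k_or_threshold - 1e-12)[1]
    if (is.na(k)) k <- p
  }
  model$selection_mode <- mode
  model$selected_k <- k
  model
}

#' Project a cohort table onto the retained components
#'
#' Centering and scaling always use the fit-time (training) statistics, so
#' transforming test rows leaks nothing. Label and reference columns are
#' carried through unchanged.
#'
#' @param model A `bp_reduction` model.
#' @param table Cohort table with the fit-time feature columns.
#' @return A data.frame: labels/references plus `PC1..PCk` score columns.
#' @export
reduce_transform <- function(model, table) {
  miss <- setdiff(model$features, names(table))
  if (length(miss) > 0) {
    stop_schema(paste0("table lacks fit-time feature column(s): ",
                       paste(utils::head(miss, 5), collapse = ", ")))
  }
  X <- as.matrix(table[model$features])
  Xs <- sweep(sweep(X, 2, model$centers), 2, model$scales, "/")
  k <- model$selected_k
  scores <- Xs %*% model$rotation[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  labs <- intersect(LABEL_COLS, names(table))
  out <- cbind(table[labs], as.data.frame(scores))
  rownames(out) <- NULL
  out
}

#' Rank original features by maximal absolute loading
#'
#' Reproduces named-feature selection semantics: features are ranked by
#' their largest absolute loading across the retained components, and the
#' top `k` names are returned. This exists alongside true component scores
#' because reduced features are often reported by original-variable names,
#' which pure principal components do not have.
#'
#' @param model A `bp_reduction` model.
#' @param k Number of feature names to keep.
#' @return Character vector of feature names, strongest first.
#' @export
loading_selection <- function(model, k = 12) {
  if (k < 1 || k > length(model$features)) stop_invalid("bad k")
  top <- model$rotation[, seq_len(model$selected_k), drop = FALSE]
  score <- apply(abs(top), 1, max)
  names(sort(score, decreasing = TRUE))[seq_len(k)]
}

#' Serialize / restore a reduction model as JSON
#'
#' @param model A `bp_reduction` model.
#' @param path File path.
#' @export
write_reduction <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_invalid("jsonlite is required for model serialization")
  }
  obj <- model
  obj$rotation <- as.data.frame(obj$rotation)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
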