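#' Kernel configuration for Gaussian-process regression
#'
#' `sigma` is the kernel length-scale in reduced-feature units (the
#' regressor shifts each input column to zero minimum and divides all
#' columns by the largest training range, so the dominant direction spans
#' \[0, 1\] and the 0.01--0.5 tuning grid covers short- to long-range
#' correlation while the relative variances of the reduced features are
#' preserved).
#' `noise_level` is the observation-noise variance added to the kernel
#' diagonal; the default 1e-4 is a numerical-stability jitter, not a fitted
#' noise estimate.
#'
#' @param family Kernel family: `"exponential"`, `"matern52"`, `"rbf"`, or
#'   `"linear"`.
#' @param sigma Positive length-scale.
#' @param noise_level Non-negative noise variance.
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(family = c("exponential", "matern52", "rbf", "linear"),
                          sigma = 0.1, noise_level = 1e-4) {
  family <- match.arg(family)
  if (sigma <= 0) stop_invalid("`sigma` must be positive")
  if (noise_level < 0) stop_invalid("`noise_level` must be >= 0")
  structure(list(family = family, sigma = sigma, noise_level = noise_level),
            class = "kernel_config")
}

cross_dist <- function(X1, X2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  sqrt(pmax(d2, 0))
}

#' Kernel (covariance) matrix between two input sets
#'
#' Exponential: `exp(-r / sigma)`. Matern 5/2:
#' `(1 + sqrt(5) r / sigma + 5 r^2 / (3 sigma^2)) exp(-sqrt(5) r / sigma)`.
#' RBF: `exp(-r^2 / (2 sigma^2))`. Linear: `1 + <x, x'>` (sigma unused).
#'
#' @param cfg A [kernel_config()].
#' @param X1,X2 Numeric matrices with matching column counts.
#' @return The `nrow(X1) x nrow(X2)` kernel matrix.
#' @export
kernel_matrix <- function(cfg, X1, X2) {
  same <- missing(X2)
  if (same) X2 <- X1
  if (cfg$family == "linear") return(1 + tcrossprod(X1, X2))
  r <- cross_dist(X1, X2)
  if (same) diag(r) <- 0 # exact unit diagonal for stationary kernels
  s <- cfg$sigma
  switch(cfg$family,
    exponential = exp(-r / s),
    matern52 = {
      q <- sqrt(5) * r / s
      (1 + q + q^2 / 3) * exp(-q)
    },
    rbf = exp(-r^2 / (2 * s^2))
  )
}

# Low-level fit on prepared matrices: returns the Cholesky factor and the
# weight vector for centred targets.
# Input scaling for the kernel metric: each column is shifted by its
# training minimum and every column is divided by the single largest
# training range. The common denominator maps the dominant input direction
# to [0, 1] (so the 0.01-0.5 length-scale grid is meaningful) while
# preserving the relative variances of the reduced features -- per-column
# normalization would inflate low-variance noise components to the same
# scale as the leading ones and drown the informative structure.
input_scaling <- function(X) {
  lo <- apply(X, 2, min)
  ranges <- apply(X, 2, max) - lo
  span <- max(ranges)
  if (span <= 0) span <- 1
  list(lo = lo, span = rep(span, ncol(X)))
}

gpr_core <- function(X, y, cfg) {
  K <- kernel_matrix(cfg, X)
  diag(K) <- diag(K) + cfg$noise_level
  L <- tryCatch(chol(K), error = function(e) {
    stop_illcond(paste0("kernel matrix is not positive definite ",
                        "(duplicated inputs with zero noise?); ",
                        "set noise_level > 0"))
  })
  alpha <- backsolve(L, forwardsolve(t(L), y))
  list(L = L, alpha = alpha)
}

extract_inputs <- function(table, input_cols = NULL) {
  if (is.null(input_cols)) {
    input_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          LABEL_COLS)
  }
  miss <- setdiff(input_cols, names(table))
  if (length(miss) > 0) {
    stop_schema(paste0("missing input column(s): ", paste(miss, collapse = ", ")))
  }
  as.matrix(table[input_cols])
}

#' Fit a Gaussian-process blood-pressure model
#'
#' Inputs are scaled with training statistics (zero-minimum shift per
#' column, one common denominator — see [kernel_config()]); targets are
#' centred on the training mean, which acts as the GP prior mean. With `noise_level = 0` the posterior mean interpolates the
#' training targets exactly.
#'
#' When the table carries a `phase` column and `train_phase` is not NULL,
#' fitting is restricted to that phase — the model of the modelled protocol
#' is built on baseline ("before") windows and then applied to the later
#' phases.
#'
#' @param train Reduced training table (see [reduce_transform()]).
#' @param target `"SBP"` or `"DBP"`; the reference column `sbp_ref` /
#'   `dbp_ref` supplies the targets in mmHg.
#' @param kernel A [kernel_config()].
#' @param train_phase Phase filter applied before fitting (default
#'   `"before"` when a phase column exists; NULL disables filtering).
#' @param input_cols Input columns (default: every numeric non-label
#'   column, i.e. the PC scores).
#' @return A fitted `bp_model`.
#' @export
gpr_fit <- function(train, target = c("DBP", "SBP"), kernel = kernel_config(),
                    train_phase = "before", input_cols = NULL) {
  target <- match.arg(target)
  if (!is.null(train_phase) && "phase" %in% names(train)) {
    sel <- train$phase == train_phase
    if (!any(sel)) stop_invalid(sprintf("no rows in phase '%s'", train_phase))
    train <- train[sel, , drop = FALSE]
  }
  ref_col <- if (target == "SBP") "sbp_ref" else "dbp_ref"
  if (!ref_col %in% names(train)) stop_schema(paste("missing", ref_col))
  y <- train[[ref_col]]
  if (any(is.na(y))) stop_invalid("missing reference values")
  if (any(y < 30 | y > 260)) {
    warning("training targets outside the physiological range [30, 260] mmHg")
  }
  X <- extract_inputs(train, input_cols)
  if (any(is.na(X))) stop_invalid("missing values in inputs")
  sc <- input_scaling(X)
  Xs <- sweep(sweep(X, 2, sc$lo), 2, sc$span, "/")
  y_mean <- mean(y)
  core <- gpr_core(Xs, y - y_mean, kernel)
  structure(
    list(target = target, kernel = kernel, input_cols = colnames(X),
         lo = sc$lo, span = sc$span, X = Xs, y_mean = y_mean,
         L = core$L, alpha = core$alpha, n_train = nrow(Xs)),
    class = "bp_model"
  )
}

#' Predict blood pressure with a fitted GP model
#'
#' @param object A `bp_model` from [gpr_fit()].
#' @param newdata Table with the model's input columns (an empty table
#'   yields an empty result).
#' @param ... Unused.
#' @return A data.frame with `estimate` (mmHg) and `sd` (posterior
#'   predictive standard deviation of the latent function, mmHg).
#' @export
predict.bp_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) {
    return(data.frame(estimate = numeric(0), sd = numeric(0)))
  }
  X <- extract_inputs(newdata, object$input_cols)
  Xs <- sweep(sweep(X, 2, object$lo), 2, object$span, "/")
  Kx <- kernel_matrix(object$kernel, Xs, object$X)
  est <- drop(Kx %*% object$alpha) + object$y_mean
  v <- forwardsolve(t(object$L), t(Kx))
  prior_var <- if (object$kernel$family == "linear") 1 + rowSums(Xs^2) else 1
  var <- pmax(prior_var - colSums(v^2), 0)
  data.frame(estimate = est, sd = sqrt(var))
}

#' Tune the kernel length-scale by cross-validated grid search
#'
#' Evaluates every `sigma` on the grid with k-fold cross-validation (seeded
#' fold assignment) and returns the configuration minimising mean CV RMSE;
#' ties break toward the smaller length-scale. The default grid is
#' 0.01--0.5 in steps of 0.01.
#'
#' @param train Reduced training table.
#' @param target `"SBP"` or `"DBP"`.
#' @param family Kernel family.
#' @param grid Candidate length-scales.
#' @param folds Number of CV folds.
#' @param noise_level Noise variance used during tuning and returned.
#' @param rng_seed Seed for fold assignment.
#' @param train_phase Phase filter (as in [gpr_fit()]).
#' @param input_cols Input columns (as in [gpr_fit()]).
#' @return The winning [kernel_config()], with the CV table in attribute
#'   `cv` (columns `sigma`, `rmse`).
#' @export
gpr_tune_sigma <- function(train, target = c("DBP", "SBP"),
                           family = c("exponential", "matern52", "rbf"),
                           grid = seq(0.01, 0.5, by = 0.01), folds = 5,
                           noise_level = 1e-4, rng_seed = 1L,
                           train_phase = "before", input_cols = NULL) {
  target <- match.arg(target)
  family <- match.arg(family)
  if (length(grid) == 0) stop_invalid("empty sigma grid")
  if (!is.null(train_phase) && "phase" %in% names(train)) {
    sel <- train$phase == train_phase
    if (any(sel)) train <- train[sel, , drop = FALSE]
  }
  n <- nrow(train)
  if (n < 2 * folds) stop_invalid("need at least 2 rows per fold")
  ref_col <- if (target == "SBP") "sbp_ref" else "dbp_ref"
  y <- train[[ref_col]]
  X <- extract_inputs(train, input_cols)
  sc <- input_scaling(X)
  Xs <- sweep(sweep(X, 2, sc$lo), 2, sc$span, "/")
  fold_id <- withr::with_seed(rng_seed, sample(rep(seq_len(folds), length.out = n)))
  rmse <- vapply(grid, function(s) {
    cfg <- kernel_config(family, s, noise_level)
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      core <- gpr_core(Xs[tr, , drop = FALSE], y[tr] - mean(y[tr]), cfg)
      Kx <- kernel_matrix(cfg, Xs[!tr, , drop = FALSE], Xs[tr, , drop = FALSE])
      pred <- drop(Kx %*% core$alpha) + mean(y[tr])
      errs[f] <- sqrt(mean((pred - y[!tr])^2))
    }
    mean(errs)
  }, numeric(1))
  best <- kernel_config(family, grid[which.min(rmse)], noise_level)
  attr(best, "cv") <- data.frame(sigma = grid, rmse = rmse)
  best
}

#' Regression error metrics
#'
#' @param estimates,references Equal-length numeric vectors (n >= 2), mmHg.
#' @return A one-row data.frame: `mean_error` (mean of estimate minus
#'   reference), `error_std` (sample SD of residuals), `rmse`, `mae`, and
#'   `r_squared` (`1 - SS_res / SS_tot`; NA when the references have zero
#'   variance).
#' @examples
#' evaluate_bp(c(121, 119), c(120, 120))
#' @export
evaluate_bp <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop_invalid("estimates and references must have equal length")
  }
  if (length(estimates) < 2) stop_invalid("need at least 2 pairs")
  res <- estimates - references
  ss_tot <- sum((references - mean(references))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  if (is.na(r2)) message("zero-variance references: r_squared not available")
  data.frame(
    mean_error = mean(res),
    error_std = stats::sd(res),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    r_squared = r2
  )
}
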