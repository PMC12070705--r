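# naive GP oracle: dense solve, no Cholesky, no scaling
gp_naive <- function(X, y, Xstar, cfg) {
  K <- kernel_matrix(cfg, X)
  diag(K) <- diag(K) + cfg$noise_level
  drop(kernel_matrix(cfg, Xstar, X) %*% solve(K, y - mean(y))) + mean(y)
}

test_that("kernel matrices are symmetric positive semi-definite", {
  X <- withr::with_seed(1, matrix(rnorm(60), 20, 3))
  for (fam in c("exponential", "matern52", "rbf")) {
    K <- kernel_matrix(kernel_config(fam, 0.7), X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-8)
    expect_equal(unname(diag(K)), rep(1, 20))
  }
  expect_error(kernel_config("rbf", -1), class = "pulsebp_invalid_argument")
})

test_that("a noise-free GP interpolates its training targets", {
  tb <- withr::with_seed(2, data.frame(x = runif(15), dbp_ref = 60 + runif(15, 0, 30)))
  m <- gpr_fit(tb, "DBP", kernel_config("exponential", 0.2, 0), train_phase = NULL)
  pr <- predict(m, tb)
  expect_lt(max(abs(pr$estimate - tb$dbp_ref)), 1e-6)
  expect_true(all(pr$sd >= 0))
  expect_lt(max(pr$sd), 1e-3)
  # single training point predicts exactly its own target
  one <- gpr_fit(tb[1, , drop = FALSE], "DBP",
                 kernel_config("matern52", 0.2, 0), train_phase = NULL)
  expect_equal(predict(one, tb[1, , drop = FALSE])$estimate, tb$dbp_ref[1],
               tolerance = 1e-9)
})

test_that("duplicated inputs with conflicting targets and zero noise fail loudly", {
  tb <- data.frame(x1 = c(1, 1, 2), x2 = c(0, 0, 1), dbp_ref = c(70, 80, 75))
  expect_error(
    gpr_fit(tb, "DBP", kernel_config("exponential", 0.1, 0), train_phase = NULL),
    class = "pulsebp_ill_conditioned"
  )
})

test_that("predictions revert to the prior mean far from the data", {
  tb <- withr::with_seed(3, data.frame(x = runif(30), dbp_ref = 70 + rnorm(30, 0, 5)))
  m <- gpr_fit(tb, "DBP", kernel_config("matern52", 0.2, 1e-4), train_phase = NULL)
  far <- data.frame(x = 100)
  expect_equal(predict(m, far)$estimate, mean(tb$dbp_ref), tolerance = 1e-6)
  # and an empty request yields an empty answer
  expect_equal(nrow(predict(m, tb[0, , drop = FALSE])), 0)
})

test_that("predictions are monotone when the target is monotone in one input", {
  tb <- data.frame(x = seq(0, 1, length.out = 40),
                   sbp_ref = 100 + 40 * seq(0, 1, length.out = 40))
  m <- gpr_fit(tb, "SBP", kernel_config("matern52", 0.3, 1e-6), train_phase = NULL)
  grid <- data.frame(x = seq(0.05, 0.95, length.out = 50))
  pr <- predict(m, grid)
  expect_true(all(diff(pr$estimate) > 0))
})

test_that("the fitted model agrees with a naive dense-solve oracle", {
  withr::with_seed(4, {
    X <- matrix(runif(40), 20, 2)
    y <- 80 + 10 * X[, 1] + rnorm(20)
  })
  tb <- data.frame(a = X[, 1], b = X[, 2], dbp_ref = y)
  new <- data.frame(a = runif(7), b = runif(7))
  cfg <- kernel_config("exponential", 0.15, 1e-3)
  m <- gpr_fit(tb, "DBP", cfg, train_phase = NULL)
  # reproduce the model's input scaling, then use the naive path
  Xs <- sweep(sweep(as.matrix(tb[c("a", "b")]), 2, m$lo), 2, m$span, "/")
  Ns <- sweep(sweep(as.matrix(new), 2, m$lo), 2, m$span, "/")
  expect_equal(predict(m, new)$estimate, gp_naive(Xs, y, Ns, cfg),
               tolerance = 1e-8)
})

test_that("cross-validated tuning recovers a known length-scale", {
  withr::with_seed(1, {
    n <- 80
    X <- matrix(runif(2 * n), n, 2)
    K <- kernel_matrix(kernel_config("matern52", 0.12), X) + diag(1e-8, n)
    y <- drop(t(chol(K)) %*% rnorm(n))
  })
  tb <- data.frame(X1 = X[, 1], X2 = X[, 2], dbp_ref = 75 + 5 * y)
  kc <- gpr_tune_sigma(tb, "DBP", "matern52", grid = seq(0.02, 0.3, by = 0.02),
                       rng_seed = 2, train_phase = NULL,
                       input_cols = c("X1", "X2"))
  expect_lte(abs(kc$sigma - 0.12), 0.02)
  kc2 <- gpr_tune_sigma(tb, "DBP", "matern52", grid = seq(0.02, 0.3, by = 0.02),
                        rng_seed = 2, train_phase = NULL,
                        input_cols = c("X1", "X2"))
  expect_identical(kc$sigma, kc2$sigma)
  expect_error(gpr_tune_sigma(tb, "DBP", grid = numeric(0), train_phase = NULL),
               class = "pulsebp_invalid_argument")
})

test_that("tuning a pure-noise target never under-reports the noise floor", {
  tb <- withr::with_seed(5, data.frame(X1 = runif(60), X2 = runif(60),
                                       dbp_ref = 75 + rnorm(60, 0, 5)))
  s <- sd(tb$dbp_ref)
  kc <- gpr_tune_sigma(tb, "DBP", "matern52", grid = c(0.05, 0.1, 0.2, 0.4),
                       rng_seed = 6, train_phase = NULL,
                       input_cols = c("X1", "X2"))
  expect_true(all(attr(kc, "cv")$rmse > 0.9 * s))
  # with a calibrated noise level the CV error sits at the noise floor
  kcn <- gpr_tune_sigma(tb, "DBP", "matern52", grid = c(0.05, 0.1, 0.2, 0.4),
                        noise_level = var(tb$dbp_ref), rng_seed = 6,
                        train_phase = NULL, input_cols = c("X1", "X2"))
  expect_true(all(abs(attr(kcn, "cv")$rmse - s) < 0.25 * s))
})

test_that("test error falls as the training set grows on law-driven data", {
  rmse_at <- function(n) {
    tb <- toy_cohort(n + 40, p = 2, seed = 7)
    sp <- split_cohort(tb, n / (n + 40), rng_seed = 8)
    m <- gpr_fit(sp$train, "SBP", kernel_config("matern52", 0.2, 1e-4),
                 train_phase = NULL, input_cols = c("ptt_mean", "ai_mean"))
    evaluate_bp(predict(m, sp$test)$estimate, sp$test$sbp_ref)$rmse
  }
  errs <- vapply(c(50, 100, 200), rmse_at, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.5)
})

test_that("evaluation metrics satisfy their defining identities", {
  ev <- evaluate_bp(c(120, 80), c(120, 80))
  expect_equal(ev$mean_error, 0)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r_squared, 1)
  ev2 <- evaluate_bp(c(121, 79), c(120, 80))
  expect_equal(ev2$mean_error, 0)
  expect_equal(ev2$rmse, 1)
  expect_equal(ev2$mae, 1)
  withr::with_seed(9, {
    for (i in 1:20) {
      est <- rnorm(40, 100, 10); ref <- rnorm(40, 100, 10)
      ev <- evaluate_bp(est, ref)
      res <- est - ref
      expect_equal(ev$rmse^2, ev$mean_error^2 + mean((res - mean(res))^2),
                   tolerance = 1e-12)
      expect_gte(ev$rmse, abs(ev$mean_error))
      expect_equal(ev$mae, mean(abs(res)), tolerance = 1e-12)
    }
  })
  expect_message(evz <- evaluate_bp(c(1, 2), c(5, 5)), "zero-variance")
  expect_true(is.na(evz$r_squared))
  expect_error(evaluate_bp(1:3, 1:4), class = "pulsebp_invalid_argument")
})
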