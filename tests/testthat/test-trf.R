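test_that("ridge at negligible penalty matches the normal-equation oracle", {
  set.seed(1)
  n <- 300; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) + rnorm(n)
  streams <- list(`1` = matrix(0, 10, 16, dimnames = list(NULL, feature_names())))
  # use the low-level solver directly against lm()
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  beta <- speechTRF:::ridge_eigen_path(crossprod(Xc), crossprod(Xc, yc), 1e-10)[[1]]
  ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(drop(beta), ols, tolerance = 1e-6)
})

test_that("ridge coefficient norm shrinks monotonically in lambda", {
  set.seed(2)
  X <- matrix(rnorm(500 * 12), 500, 12)
  y <- X %*% rnorm(12) + rnorm(500)
  Xc <- sweep(X, 2, colMeans(X))
  lams <- 10^seq(-2, 4, length.out = 8)
  betas <- speechTRF:::ridge_eigen_path(crossprod(Xc),
                                        crossprod(Xc, y - mean(y)), lams)
  norms <- vapply(betas, function(b) sqrt(sum(b^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("singular designs at lambda zero raise an actionable error", {
  X <- cbind(1:10, (1:10) * 2)   # exactly collinear
  Xc <- sweep(X, 2, colMeans(X))
  expect_error(
    speechTRF:::ridge_eigen_path(crossprod(Xc), crossprod(Xc, rnorm(10)), 0),
    "lambda > 0")
})

test_that("noiseless simulation is recovered exactly", {
  sc <- make_encoding_scenario(n_electrodes = 3, noise_sd = 0, seed = 11,
                               n_train = 24, n_test = 5)
  fit <- fit_trf(sc$ed, lambda_grid = 10^seq(-6, 0, length.out = 7), seed = 3)
  r2 <- evaluate_heldout(fit, sc$ed)
  expect_true(all(r2 > 0.99))
  for (e in 1:3)
    expect_gt(cor(fit$beta[, e], sc$truth$beta[, e]), 0.99)
})

test_that("pure-noise responses earn near-zero held-out R2", {
  sc <- make_encoding_scenario(n_electrodes = 4, noise_sd = 1, seed = 12,
                               n_train = 20, n_test = 5)
  ed <- sc$ed
  set.seed(99)
  ed$train$Y <- matrix(rnorm(length(ed$train$Y)), nrow(ed$train$Y))
  ed$test$Y <- matrix(rnorm(length(ed$test$Y)), nrow(ed$test$Y))
  ed$cache <- new.env()    # moments depend on Y
  fit <- fit_trf(ed, seed = 4)
  expect_true(all(evaluate_heldout(fit, ed) < 0.05))
})

test_that("held-out R2 follows the correlation conventions", {
  sc <- make_encoding_scenario(n_electrodes = 2, noise_sd = 0.5, seed = 13,
                               n_train = 12, n_test = 4)
  fit <- fit_trf(sc$ed, seed = 5)
  pred <- predict(fit, sc$ed, which = "test")
  # prediction identical to the response: R2 = 1
  ed2 <- sc$ed
  ed2$test$Y <- pred
  expect_equal(evaluate_heldout(fit, ed2), c(1, 1), tolerance = 1e-12)
  # constant prediction: R2 = 0 by convention
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(evaluate_heldout(fit0, sc$ed), c(0, 0))
})

test_that("parameter recovery degrades monotonically with noise", {
  cors <- vapply(c(0, 1, 4), function(ns) {
    sc <- make_encoding_scenario(n_electrodes = 2, noise_sd = ns, seed = 14,
                                 n_train = 14, n_test = 3)
    fit <- fit_trf(sc$ed, lambda_grid = 10^seq(-4, 2, length.out = 5), seed = 6)
    mean(vapply(1:2, function(e)
      cor(fit$beta[, e], sc$truth$beta[, e]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("cross-condition prediction is consistent and type-checked", {
  sc <- make_encoding_scenario(n_electrodes = 2, noise_sd = 0.5, seed = 15,
                               n_train = 14, n_test = 4)
  fit <- fit_trf(sc$ed, seed = 7)
  expect_equal(cross_condition_predict(fit, sc$ed), evaluate_heldout(fit, sc$ed))
  fit2 <- fit
  fit2$features <- c(fit$features[-1], "not_a_feature")
  expect_error(cross_condition_predict(fit2, sc$ed), "not_a_feature")
})

test_that("weight profiles and their correlations behave at the edges", {
  sc <- make_encoding_scenario(n_electrodes = 2, noise_sd = 0.5, seed = 16,
                               n_train = 12, n_test = 3)
  fit <- fit_trf(sc$ed, seed = 8)
  p1 <- weight_profile(fit, 1)
  expect_length(p1, 16)
  expect_equal(correlate_profiles(p1, p1), 1)
  expect_equal(correlate_profiles(p1, -p1), -1)
  expect_error(correlate_profiles(p1[1:2], p1[1:2]), ">= 3")
})

test_that("profile permutation null is centred and deterministic", {
  set.seed(9)
  P1 <- matrix(rnorm(20 * 16), 20)
  P2 <- matrix(rnorm(20 * 16), 20)
  n1 <- profile_permutation_null(P1, P2, n_shuffles = 50, seed = 10)
  n2 <- profile_permutation_null(P1, P2, n_shuffles = 50, seed = 10)
  expect_identical(n1$null, n2$null)
  expect_length(n1$null, 1000)
  expect_lt(abs(mean(n1$null)), 0.1)
  expect_true(n1$q95 > 0 && n1$q95 < 1)
})
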