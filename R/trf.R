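#' Bundle training and held-out data for encoding models
#'
#' Packages the lagged design matrices and response matrices for one
#' stimulus condition: the training sentences (single presentations) and
#' the held-out test sentences (responses averaged over repeated
#' presentations). A moment cache (cross-products per cross-validation
#' fold) is attached so that nested models over feature subsets reuse the
#' same expensive computations via sub-indexing.
#'
#' @param streams_train,streams_test named lists of (scaled) feature-stream
#'   matrices, names = sentence ids.
#' @param Y_train response matrix `frames x electrodes` aligned with
#'   `assemble_design(streams_train, ...)` row order.
#' @param Y_test held-out response matrix, repeat-averaged, aligned with
#'   `assemble_design(streams_test, ...)`.
#' @param n_lags,pre,post design parameters (see [assemble_design()]).
#' @return object of class `encoding_data`.
#' @export
build_encoding_data <- function(streams_train, Y_train, streams_test, Y_test,
                                n_lags = 60, pre = 50, post = 60) {
  dtr <- assemble_design(streams_train, names(streams_train) %||%
                           seq_along(streams_train), n_lags, pre, post)
  dte <- assemble_design(streams_test, names(streams_test) %||%
                           seq_along(streams_test), n_lags, pre, post)
  stopifnot(nrow(dtr$X) == nrow(Y_train), nrow(dte$X) == nrow(Y_test))
  structure(list(train = list(design = dtr, Y = as.matrix(Y_train)),
                 test = list(design = dte, Y = as.matrix(Y_test)),
                 features = dtr$features, n_lags = n_lags,
                 streams_train = streams_train, streams_test = streams_test,
                 pre = pre, post = post,
                 cache = new.env(parent = emptyenv())),
            class = "encoding_data")
}

# deterministic sentence-level fold assignment
fold_assignment <- function(ids, cv_folds, seed) {
  u <- unique(ids)
  local_rng(seed)
  f <- stats::setNames(sample(rep_len(seq_len(cv_folds), length(u))), u)
  f[as.character(ids)]
}

# cross-product moments of the full training design, total and per fold,
# cached on the encoding_data by (cv_folds, seed)
design_moments <- function(data, cv_folds, seed) {
  key <- paste0("m_", cv_folds, "_", seed)
  if (!is.null(data$cache[[key]])) return(data$cache[[key]])
  X <- data$train$design$X
  Y <- data$train$Y
  folds <- fold_assignment(data$train$design$sentence, cv_folds, seed)
  m <- list(folds = folds, cv_folds = cv_folds,
            XtX = crossprod(X), Xty = crossprod(X, Y),
            xs = colSums(X), ys = colSums(Y), n = nrow(X))
  m$fold <- lapply(seq_len(cv_folds), function(k) {
    r <- folds == k
    Xk <- X[r, , drop = FALSE]
    list(rows = which(r), XtX = crossprod(Xk),
         Xty = crossprod(Xk, Y[r, , drop = FALSE]),
         xs = colSums(Xk), ys = colSums(Y[r, , drop = FALSE]), n = sum(r))
  })
  data$cache[[key]] <- m
  m
}

# ridge solutions for all lambdas and responses from centered moments
# returns list(beta = p x E per lambda, eigen d range)
ridge_eigen_path <- function(XtXc, Xtyc, lambdas) {
  ev <- eigen(XtXc, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- crossprod(ev$vectors, Xtyc)      # p x E
  if (any(lambdas <= 0) && min(d) < 1e-10 * max(d, 1))
    stop("design is singular at lambda = 0; use lambda > 0")
  lapply(lambdas, function(l) ev$vectors %*% (U / (d + l)))
}

#' Fit a ridge-regularized temporal receptive field model
#'
#' Per electrode, predicts the HFA response as a linear combination of
#' lagged speech features, `HFA(t) = x0 + sum_f sum_l beta(l,f) X(f,t-l)`.
#' The ridge penalty is selected per electrode by inner cross-validation at
#' sentence granularity (folds never split a sentence, preventing temporal
#' leakage): the grid value maximizing the mean held-out fold correlation
#' wins, and the final weights are refit on all training rows at that
#' penalty. All electrodes share the design, so the expensive
#' cross-products are computed once per fold and solved for every electrode
#' and penalty jointly through an eigendecomposition.
#'
#' @param data an `encoding_data`.
#' @param features feature subset to fit (default: all).
#' @param lambda_grid ridge penalties (default 10 log-spaced in
#'   `[1e-2, 1e6]`).
#' @param cv_folds inner folds (default 5).
#' @param seed fold-assignment seed.
#' @return object of class `trf_fit`: `beta` (`(features*n_lags) x
#'   electrodes`), `intercept`, `lambda` (per electrode), `features`,
#'   `n_lags`, `cv_corr` (`lambda x electrode` mean fold correlations).
#' @export
fit_trf <- function(data, features = data$features,
                    lambda_grid = 10^seq(-2, 6, length.out = 10),
                    cv_folds = 5, seed = 1) {
  stopifnot(inherits(data, "encoding_data"))
  m <- design_moments(data, cv_folds, seed)
  cols <- design_cols(data$train$design, features)
  X <- data$train$design$X
  Y <- data$train$Y
  n_e <- ncol(Y)
  nl <- length(lambda_grid)

  corr_sum <- matrix(0, nl, n_e)
  corr_cnt <- matrix(0, nl, n_e)
  for (k in seq_len(cv_folds)) {
    fk <- m$fold[[k]]
    n_tr <- m$n - fk$n
    xbar <- (m$xs[cols] - fk$xs[cols]) / n_tr
    ybar <- (m$ys - fk$ys) / n_tr
    XtXc <- (m$XtX[cols, cols] - fk$XtX[cols, cols]) - n_tr * tcrossprod(xbar)
    Xtyc <- (m$Xty[cols, , drop = FALSE] - fk$Xty[cols, , drop = FALSE]) -
      n_tr * outer(xbar, ybar)
    betas <- ridge_eigen_path(XtXc, Xtyc, lambda_grid)
    Xf <- sweep(X[fk$rows, cols, drop = FALSE], 2, xbar)
    Yf <- Y[fk$rows, , drop = FALSE]
    for (li in seq_len(nl)) {
      pred <- Xf %*% betas[[li]]
      r <- suppressWarnings(
        vapply(seq_len(n_e), function(e) stats::cor(pred[, e], Yf[, e]),
               numeric(1)))
      ok <- is.finite(r)
      corr_sum[li, ok] <- corr_sum[li, ok] + r[ok]
      corr_cnt[li, ok] <- corr_cnt[li, ok] + 1
    }
  }
  cv_corr <- corr_sum / pmax(corr_cnt, 1)
  cv_corr[corr_cnt == 0] <- -Inf
  best <- apply(cv_corr, 2, which.max)

  xbar <- m$xs[cols] / m$n
  ybar <- m$ys / m$n
  XtXc <- m$XtX[cols, cols] - m$n * tcrossprod(xbar)
  Xtyc <- m$Xty[cols, , drop = FALSE] - m$n * outer(xbar, ybar)
  betas <- ridge_eigen_path(XtXc, Xtyc, lambda_grid)
  beta <- matrix(0, length(cols), n_e)
  for (e in seq_len(n_e)) beta[, e] <- betas[[best[e]]][, e]
  intercept <- ybar - drop(crossprod(beta, xbar))

  structure(list(beta = beta, intercept = intercept,
                 lambda = lambda_grid[best], lambda_grid = lambda_grid,
                 features = features, n_lags = data$n_lags,
                 cv_corr = cv_corr, cv_folds = cv_folds, seed = seed),
            class = "trf_fit")
}

#' @export
print.trf_fit <- function(x, ...) {
  cat("<trf_fit> ", length(x$features), " features x ", x$n_lags,
      " lags, ", ncol(x$beta), " electrodes; lambda in [",
      format(min(x$lambda), digits = 3), ", ",
      format(max(x$lambda), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Predict from a TRF fit
#' @param object a `trf_fit`.
#' @param data an `encoding_data`.
#' @param which `"test"` or `"train"` rows.
#' @param ... unused.
#' @return matrix `frames x electrodes` of predicted HFA.
#' @export
predict.trf_fit <- function(object, data, which = "test", ...) {
  d <- if (which == "test") data$test$design else data$train$design
  cols <- design_cols(d, object$features)
  d$X[, cols, drop = FALSE] %*% object$beta +
    matrix(object$intercept, nrow(d$X), ncol(object$beta), byrow = TRUE)
}

#' Held-out correlation R^2 of a TRF fit
#'
#' Predictions are concatenated across the held-out test sentences and
#' correlated per electrode with the repeat-averaged neural response;
#' R^2 is the squared correlation, clipped to 0 when the correlation is
#' negative or undefined (constant prediction).
#'
#' @param fit a `trf_fit`.
#' @param data an `encoding_data` (its `test` slot is used).
#' @return numeric vector of per-electrode R^2 in `[0, 1]`.
#' @export
evaluate_heldout <- function(fit, data) {
  pred <- predict(fit, data, which = "test")
  Y <- data$test$Y
  r <- suppressWarnings(vapply(seq_len(ncol(Y)), function(e)
    stats::cor(pred[, e], Y[, e]), numeric(1)))
  r[!is.finite(r)] <- 0
  pmax(r, 0)^2
}

#' Cross-condition generalization of a TRF fit
#'
#' Applies a model trained in one listening condition (language) to the
#' held-out data of another, after checking that the feature spaces match.
#'
#' @param fit a `trf_fit` trained on condition A.
#' @param data_other `encoding_data` of condition B.
#' @return per-electrode held-out R^2 on condition B.
#' @export
cross_condition_predict <- function(fit, data_other) {
  if (!identical(fit$features, intersect(data_other$features, fit$features)) ||
      !all(fit$features %in% data_other$features)) {
    d1 <- setdiff(fit$features, data_other$features)
    stop("feature spaces differ across conditions: ",
         paste(d1, collapse = ", "))
  }
  evaluate_heldout(fit, data_other)
}

#' Per-feature weight profile of a TRF fit
#'
#' Finds the lag with the maximum feature-averaged absolute weight
#' (earliest lag on ties) and returns, per feature, the mean weight over
#' the 0.05 s (5-sample) window centred on that lag.
#'
#' @param fit a `trf_fit`.
#' @param electrode electrode index.
#' @return named numeric vector, one scalar per feature.
#' @export
weight_profile <- function(fit, electrode = 1) {
  B <- matrix(fit$beta[, electrode], nrow = fit$n_lags)  # lags x features
  prof_lag <- which.max(rowMeans(abs(B)))                # ties: earliest
  win <- max(1, prof_lag - 2):min(fit$n_lags, prof_lag + 2)
  stats::setNames(colMeans(B[win, , drop = FALSE]), fit$features)
}

#' Correlate two weight profiles
#' @param p1,p2 profiles from [weight_profile()] (same features, >= 3).
#' @return Pearson correlation.
#' @export
correlate_profiles <- function(p1, p2) {
  if (length(p1) < 3) stop("need >= 3 features for a stable correlation")
  stopifnot(length(p1) == length(p2))
  stats::cor(p1, p2)
}

#' Permutation null for cross-condition weight-profile correlations
#'
#' For each electrode, shuffles the entries of one condition's profile and
#' correlates with the other condition's profile, `n_shuffles` times;
#' pooled draws form the chance distribution, summarized by its 95th
#' percentile. The identity permutation is not excluded, so r = 1 draws
#' are possible at low feature counts.
#'
#' @param profiles1,profiles2 matrices `electrodes x features`.
#' @param n_shuffles shuffles per electrode (default 10).
#' @param seed integer seed.
#' @return list `null` (pooled draws), `q95`, `observed` (per-electrode r).
#' @export
profile_permutation_null <- function(profiles1, profiles2, n_shuffles = 10,
                                     seed = 1) {
  stopifnot(nrow(profiles1) == nrow(profiles2), nrow(profiles1) >= 2)
  local_rng(seed)
  n_e <- nrow(profiles1)
  obs <- vapply(seq_len(n_e), function(e)
    stats::cor(profiles1[e, ], profiles2[e, ]), numeric(1))
  null <- numeric(0)
  for (e in seq_len(n_e))
    for (s in seq_len(n_shuffles))
      null <- c(null, stats::cor(profiles1[e, ],
                                 profiles2[e, sample.int(ncol(profiles2))]))
  list(null = null, q95 = stats::quantile(null, 0.95, names = FALSE),
       observed = obs)
}
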