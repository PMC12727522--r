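#' The nested unique-variance scheme table
#'
#' One row per feature family, each mapping to the exact pair of nested
#' models whose held-out R^2 difference defines that family's unique
#' variance: acoustic--phonetic families (sentence onset, peakRate,
#' consonant features, vowel formants) compare the full model against the
#' full model minus the family; word onset compares acoustic+word-onset
#' against the acoustic model; word frequency and word length each add
#' their feature on top of acoustic+word-onset; phoneme surprisal adds
#' surprisal to the acoustic model; and the combined word-feature family
#' compares the full model against the acoustic model.
#'
#' @return data.frame with columns `family`, `type`
#'   (`"acoustic"`/`"word"`/`"combined"`) and list-columns `full`,
#'   `reduced`, `family_features`.
#' @export
family_schemes <- function() {
  ac <- acoustic_features()
  full <- feature_names()
  row <- function(family, type, full_set, reduced_set) {
    data.frame(family = family, type = type,
               full = I(list(full_set)), reduced = I(list(reduced_set)),
               family_features = I(list(setdiff(full_set, reduced_set))))
  }
  cons <- c("dorsal", "coronal", "labial", "nasal", "plosive", "fricative")
  fmts <- c("F1", "F2", "F3", "F4")
  rbind(
    row("sentence_onset", "acoustic", full, setdiff(full, "sentence_onset")),
    row("peakRate", "acoustic", full, setdiff(full, "peakRate")),
    row("consonant", "acoustic", full, setdiff(full, cons)),
    row("formant", "acoustic", full, setdiff(full, fmts)),
    row("word_onset", "word", c(ac, "word_onset"), ac),
    row("word_frequency", "word", c(ac, "word_onset", "word_frequency"),
        c(ac, "word_onset")),
    row("word_length", "word", c(ac, "word_onset", "word_length"),
        c(ac, "word_onset")),
    row("phoneme_surprisal", "word", c(ac, "phoneme_surprisal"), ac),
    row("word_combined", "combined", full, ac)
  )
}

#' Unique variance (delta R^2) of a feature family
#'
#' Fits the scheme's full and reduced models on identical training rows
#' with identical sentence-level cross-validation folds (the ridge penalty
#' is selected independently per model), evaluates both on the identical
#' held-out repeat-averaged sentences, and returns the per-electrode
#' difference of correlation R^2. Negative values are possible and
#' meaningful (the extra features can hurt out-of-sample).
#'
#' @param data an `encoding_data`.
#' @param scheme one row of [family_schemes()] (or a list with `full`,
#'   `reduced` character vectors).
#' @param lambda_grid,cv_folds,seed passed to [fit_trf()].
#' @param fits optional environment cache of fitted models keyed by
#'   feature set (shared across schemes).
#' @return list with `delta_r2`, `r2_full`, `r2_reduced` (per electrode)
#'   and the two `trf_fit` objects.
#' @export
unique_variance <- function(data, scheme,
                            lambda_grid = 10^seq(-2, 6, length.out = 10),
                            cv_folds = 5, seed = 1, fits = NULL) {
  full <- unlist(scheme$full)
  reduced <- unlist(scheme$reduced)
  if (!all(reduced %in% full))
    stop("invalid scheme: reduced set is not a subset of the full set")
  get_fit <- function(feats) {
    key <- paste(sort(feats), collapse = "|")
    if (!is.null(fits) && !is.null(fits[[key]])) return(fits[[key]])
    f <- fit_trf(data, feats, lambda_grid, cv_folds, seed)
    f$r2 <- evaluate_heldout(f, data)
    if (!is.null(fits)) fits[[key]] <- f
    f
  }
  ff <- get_fit(full)
  fr <- get_fit(reduced)
  list(delta_r2 = ff$r2 - fr$r2, r2_full = ff$r2, r2_reduced = fr$r2,
       fit_full = ff, fit_reduced = fr)
}

# circularly rotate the padded per-sentence blocks of the family features
# and return their lagged columns (train or test side)
family_lag_blocks <- function(streams, fam, n_lags, pre, post, offsets = NULL) {
  parts <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]][, fam, drop = FALSE]
    sp <- rbind(matrix(0, pre, ncol(s)), s, matrix(0, post, ncol(s)))
    if (!is.null(offsets) && offsets[i] %% nrow(sp) != 0) {
      o <- offsets[i] %% nrow(sp)
      sp <- sp[c((nrow(sp) - o + 1L):nrow(sp), 1L:(nrow(sp) - o)), , drop = FALSE]
    }
    lag_matrix(sp, n_lags)
  })
  do.call(rbind, parts)
}

#' Circular-shift permutation significance of unique variance
#'
#' Builds the null distribution of a family's delta R^2 by circularly
#' shifting the family's feature streams in time (jointly, per sentence
#' block, before lag expansion; offsets are uniform with at least
#' `min_shift_s` from the identity so near-identity shifts are excluded),
#' refitting the full-side model at each electrode's selected ridge
#' penalty, and re-evaluating held-out R^2. The reduced model does not
#' contain the family, so its R^2 is unchanged under the null. The
#' one-sided p-value counts permuted values greater than or equal to the
#' observed one (so the identity shift would reproduce the observed value
#' exactly and p is never 0); the minimum reportable p is `1/n_perms`.
#'
#' @param data an `encoding_data`.
#' @param scheme one row of [family_schemes()].
#' @param n_perms number of permutations (default 300).
#' @param seed integer seed.
#' @param uv result of [unique_variance()] for this scheme (computed if
#'   missing).
#' @param min_shift_s minimum shift in seconds (default 0.5).
#' @param lambda_grid,cv_folds passed through when `uv` must be computed.
#' @return list with `p` (per electrode), `delta_true`, `delta_perm`
#'   (`electrodes x n_perms`), `n_perms`.
#' @export
permutation_significance <- function(data, scheme, n_perms = 300, seed = 1,
                                     uv = NULL, min_shift_s = 0.5,
                                     lambda_grid = 10^seq(-2, 6, length.out = 10),
                                     cv_folds = 5) {
  if (n_perms < 1) stop("n_perms must be >= 1")
  if (is.null(uv))
    uv <- unique_variance(data, scheme, lambda_grid, cv_folds, seed)
  fam <- unlist(scheme$family_features)
  reduced <- unlist(scheme$reduced)
  full <- unlist(scheme$full)

  m <- design_moments(data, uv$fit_full$cv_folds, uv$fit_full$seed)
  dtr <- data$train$design
  cols_red <- design_cols(dtr, reduced)
  X <- dtr$X
  Y <- data$train$Y
  n <- nrow(X)
  Xr <- X[, cols_red, drop = FALSE]
  dte <- data$test$design
  Xr_te <- dte$X[, design_cols(dte, reduced), drop = FALSE]
  Yte <- data$test$Y

  # static moment blocks of the reduced columns
  XtX_rr <- m$XtX[cols_red, cols_red]
  Xty_r <- m$Xty[cols_red, , drop = FALSE]
  xs_r <- m$xs[cols_red]
  ybar <- m$ys / n

  lam <- uv$fit_full$lambda
  lam_groups <- split(seq_along(lam), lam)
  p_r <- length(cols_red)
  p_f <- length(fam) * data$n_lags

  # per-sentence block lengths and admissible offsets
  tr_ids <- names(data$streams_train) %||% seq_along(data$streams_train)
  te_ids <- names(data$streams_test) %||% seq_along(data$streams_test)
  blk_tr <- vapply(data$streams_train, nrow, integer(1)) + data$pre + data$post
  blk_te <- vapply(data$streams_test, nrow, integer(1)) + data$pre + data$post
  min_f <- as.integer(round(min_shift_s * 100))
  if (any(blk_tr < 2 * min_f + 2))
    stop("sentences too short for a ", min_shift_s, " s minimum shift")

  local_rng(seed + 31L)
  delta_perm <- matrix(0, ncol(Y), n_perms)
  for (k in seq_len(n_perms)) {
    off_tr <- vapply(blk_tr, function(b)
      sample(min_f:(b - min_f), 1), integer(1))
    off_te <- vapply(blk_te, function(b)
      sample(min_f:(b - min_f), 1), integer(1))
    Ftr <- family_lag_blocks(data$streams_train, fam, data$n_lags,
                             data$pre, data$post, off_tr)
    Fte <- family_lag_blocks(data$streams_test, fam, data$n_lags,
                             data$pre, data$post, off_te)
    xs_f <- colSums(Ftr)
    xbar <- c(xs_r, xs_f) / n
    XtX <- rbind(cbind(XtX_rr, crossprod(Xr, Ftr)),
                 cbind(matrix(0, p_f, p_r), crossprod(Ftr)))
    XtX[(p_r + 1):(p_r + p_f), 1:p_r] <- t(XtX[1:p_r, (p_r + 1):(p_r + p_f)])
    XtXc <- XtX - n * tcrossprod(xbar)
    Xtyc <- rbind(Xty_r, crossprod(Ftr, Y)) - n * outer(xbar, ybar)

    pred <- matrix(0, nrow(Yte), ncol(Y))
    Xte_c <- cbind(sweep(Xr_te, 2, xbar[1:p_r]),
                   sweep(Fte, 2, xbar[(p_r + 1):(p_r + p_f)]))
    for (g in seq_along(lam_groups)) {
      es <- lam_groups[[g]]
      l <- lam[es[1]]
      R <- chol(XtXc + diag(l, p_r + p_f))
      beta <- backsolve(R, forwardsolve(t(R), Xtyc[, es, drop = FALSE]))
      pred[, es] <- Xte_c %*% beta +
        matrix(ybar[es], nrow(Yte), length(es), byrow = TRUE)
    }
    r <- suppressWarnings(vapply(seq_len(ncol(Y)), function(e)
      stats::cor(pred[, e], Yte[, e]), numeric(1)))
    r[!is.finite(r)] <- 0
    delta_perm[, k] <- pmax(r, 0)^2 - uv$r2_reduced
  }
  p <- vapply(seq_len(ncol(Y)), function(e)
    max(1L, sum(delta_perm[e, ] >= uv$delta_r2[e])) / n_perms, numeric(1))
  list(p = p, delta_true = uv$delta_r2, delta_perm = delta_perm,
       n_perms = n_perms)
}

#' Unique-variance partition over all families
#'
#' Runs [unique_variance()] for every scheme (model fits shared across
#' schemes through a cache) and optionally the circular-shift permutation
#' test, returning one tidy table.
#'
#' @param data an `encoding_data`.
#' @param schemes scheme table (default [family_schemes()]).
#' @param n_perms permutations per family (0 = skip significance).
#' @param lambda_grid,cv_folds,seed passed to the fitters.
#' @return data.frame: `electrode, family, type, delta_r2, r2_full,
#'   r2_reduced` and `p` when permutations were run.
#' @export
variance_partition <- function(data, schemes = family_schemes(), n_perms = 0,
                               lambda_grid = 10^seq(-2, 6, length.out = 10),
                               cv_folds = 5, seed = 1) {
  fits <- new.env(parent = emptyenv())
  out <- lapply(seq_len(nrow(schemes)), function(i) {
    sc <- schemes[i, ]
    uv <- unique_variance(data, sc, lambda_grid, cv_folds, seed, fits = fits)
    df <- data.frame(electrode = seq_along(uv$delta_r2), family = sc$family,
                     type = sc$type, delta_r2 = uv$delta_r2,
                     r2_full = uv$r2_full, r2_reduced = uv$r2_reduced)
    if (n_perms > 0) {
      ps <- permutation_significance(data, sc, n_perms, seed, uv = uv,
                                     lambda_grid = lambda_grid,
                                     cv_folds = cv_folds)
      df$p <- ps$p
    }
    df
  })
  do.call(rbind, out)
}

#' Printed significance gates for unique-variance summaries
#'
#' Adds the two published gates as boolean flags: `pass_uv` (model R^2 >
#' 0.05 and delta R^2 > 0.001, strict inequalities) used for
#' unique-variance box plots, and `pass_profile` (model R^2 > 0.1) used
#' for weight-profile analyses.
#'
#' @param partition data.frame from [variance_partition()].
#' @return the table with `pass_uv` and `pass_profile` columns.
#' @export
significance_gates <- function(partition) {
  k <- trf_constants()
  partition$pass_uv <- partition$r2_full > k$r2_gate_uv &
    partition$delta_r2 > k$duv_gate
  partition$pass_profile <- partition$r2_full > k$r2_gate_profile
  partition
}
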