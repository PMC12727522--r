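#' Extract word and within-word syllable boundary events
#'
#' One event per syllable onset, labelled `"word"` when the onset is also a
#' word onset and `"within"` otherwise. Events are flagged, not dropped:
#' word events of single-syllable words and all events of sentence-initial
#' words are marked excluded, per the decoding protocol.
#'
#' @param sentences list of `annotated_sentence` (acoustics rendered if the
#'   mel windows are wanted downstream).
#' @return data.frame: `event_id, sentence, time, frame, label, excluded,
#'   reason` plus `dip`/`ambiguous` when the sentence has rendered
#'   acoustics.
#' @export
extract_events <- function(sentences) {
  out <- lapply(sentences, function(s) {
    wf <- time_to_frame(s$words$onset)
    sf <- time_to_frame(s$syllable_onsets)
    if (!all(wf %in% sf))
      stop("annotation error in sentence ", s$id,
           ": word onset not on a syllable onset")
    wi <- findInterval(s$syllable_onsets + 1e-9, s$words$onset)
    is_word <- sf %in% wf
    single <- s$words$n_syllables[wi] == 1
    first_word <- wi == 1
    excluded <- (is_word & single) | first_word
    reason <- rep("", length(sf))
    reason[is_word & single] <- "single_syllable_word"
    reason[first_word] <- "sentence_onset_word"
    df <- data.frame(sentence = s$id, time = s$syllable_onsets, frame = sf,
                     label = ifelse(is_word, "word", "within"),
                     excluded = excluded, reason = reason)
    if (!is.null(s$boundaries)) {
      df$dip <- s$boundaries$dip
      df$ambiguous <- s$boundaries$ambiguous
    }
    df
  })
  ev <- do.call(rbind, out)
  ev$event_id <- seq_len(nrow(ev))
  ev
}

#' Sample retained boundary events to fixed class totals
#'
#' @param events data.frame from [extract_events()].
#' @param n_word,n_within class totals to sample (without replacement) from
#'   the non-excluded events.
#' @param seed integer seed.
#' @return the sampled events, ordered by event id.
#' @export
sample_events <- function(events, n_word, n_within, seed = 1) {
  local_rng(seed)
  ok <- events[!events$excluded, ]
  w <- ok[ok$label == "word", ]
  s <- ok[ok$label == "within", ]
  if (nrow(w) < n_word || nrow(s) < n_within)
    stop("not enough events: have ", nrow(w), " word / ", nrow(s),
         " within, need ", n_word, " / ", n_within)
  out <- rbind(w[sample.int(nrow(w), n_word), ],
               s[sample.int(nrow(s), n_within), ])
  out[order(out$event_id), ]
}

#' Mel-spectrogram windows around boundary events
#'
#' Vectorizes the 80-band mel-spectrogram over the 0.2 s window centred on
#' each event (frames `e - half .. e + half - 1`). Events whose window
#' leaves the sentence are dropped with a message.
#'
#' @param sentences list of rendered sentences (indexed by `sentence` id).
#' @param events events data.frame.
#' @param half window half-width in frames (default 10).
#' @return list `X` (`events x (80 * 2 half)` matrix), `events` (the rows
#'   retained, same order).
#' @export
event_windows_mel <- function(sentences, events, half = 10) {
  by_id <- stats::setNames(sentences, vapply(sentences, function(s)
    as.character(s$id), character(1)))
  keep <- logical(nrow(events))
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    s <- by_id[[as.character(events$sentence[i])]]
    if (is.null(s$mel)) stop("sentence ", events$sentence[i],
                             " has no rendered mel-spectrogram")
    f <- events$frame[i]
    if (f - half < 1 || f + half - 1 > ncol(s$mel)) next
    keep[i] <- TRUE
    rows[[i]] <- as.vector(s$mel[, (f - half):(f + half - 1)])
  }
  if (any(!keep))
    message(sum(!keep), " event(s) dropped: window outside sentence")
  list(X = do.call(rbind, rows[keep]), events = events[keep, ])
}

#' Neural-activity windows around boundary events
#'
#' Cuts the `(-0.2, +0.4)` s window (frames `e - pre .. e + post - 1`) of
#' every electrode's HFA around each event and vectorizes electrode x time
#' (electrode-major). Events too close to the recording edges are dropped
#' with a message.
#'
#' @param recording a `neural_recording` with an alignment table.
#' @param events events data.frame (frames are sentence-relative to speech
#'   onset).
#' @param pre,post window frames before/after the boundary (default 20/40).
#' @param electrodes electrode subset (default all).
#' @return list `X` (`events x (electrodes * (pre + post))`), `events`.
#' @export
event_windows_neural <- function(recording, events, pre = 20, post = 40,
                                 electrodes = seq_len(nrow(recording$hfa))) {
  al <- recording$alignment
  al <- al[!duplicated(al$sentence), ]      # first presentation per sentence
  onset <- stats::setNames(al$onset, as.character(al$sentence))
  keep <- logical(nrow(events))
  rows <- vector("list", nrow(events))
  n_fr <- ncol(recording$hfa)
  for (i in seq_len(nrow(events))) {
    o <- onset[as.character(events$sentence[i])]
    if (is.na(o)) next
    f <- o + events$frame[i] - 1L
    if (f - pre < 1 || f + post - 1 > n_fr) next
    keep[i] <- TRUE
    rows[[i]] <- as.vector(t(recording$hfa[electrodes,
                                           (f - pre):(f + post - 1), drop = FALSE]))
  }
  if (any(!keep))
    message(sum(!keep), " event(s) dropped: window outside recording")
  list(X = do.call(rbind, rows[keep]), events = events[keep, ],
       n_electrodes = length(electrodes), n_frames = pre + post)
}

# PCA retaining the smallest k with cumulative variance > var_frac;
# works from the covariance (p <= n) or Gram (n < p) side.
pca_fit <- function(X, var_frac = 0.9) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (p <= n) {
    ev <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    rot <- ev$vectors
  } else {
    ev <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(ev$values, 0)
    keep <- vals > 1e-12 * max(vals)
    rot <- crossprod(Xc, ev$vectors[, keep, drop = FALSE]) /
      rep(sqrt(vals[keep] * (n - 1)), each = p)
    vals <- vals[keep]
  }
  cum <- cumsum(vals) / sum(vals)
  k <- which(cum > var_frac)[1]
  if (is.na(k)) k <- length(vals)
  list(center = ctr, rotation = rot[, seq_len(k), drop = FALSE],
       values = vals, k = k)
}

pca_project <- function(pca, X) sweep(X, 2, pca$center) %*% pca$rotation

#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUC of `scores` for the positive class, with
#' ties handled by midranks.
#' @param scores numeric classifier scores.
#' @param labels binary labels (1/"word" = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as.integer(labels == 1 | labels == "word" | labels == TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment (each fold gets both classes)
stratified_folds <- function(labels, folds, seed) {
  local_rng(seed)
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  tab <- table(f, labels)
  if (any(tab == 0))
    stop("stratified folding impossible: a fold would have one class only")
  f
}

# L1-regularized logistic regression with the penalty chosen on an inner
# 80/20 split of the training data, refit on all training rows
l1_logistic <- function(X, y, seed = 1, n_lambda = 8) {
  local_rng(seed)
  path <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                         nlambda = n_lambda, lambda.min.ratio = 0.01)
  lams <- path$lambda
  hold <- sample.int(nrow(X), max(2, round(0.2 * nrow(X))))
  while (length(unique(y[-hold])) < 2 || length(unique(y[hold])) < 2)
    hold <- sample.int(nrow(X), max(2, round(0.2 * nrow(X))))
  inner <- glmnet::glmnet(X[-hold, , drop = FALSE], y[-hold],
                          family = "binomial", alpha = 1, lambda = lams)
  pr <- stats::predict(inner, X[hold, , drop = FALSE], type = "response")
  auc <- apply(pr, 2, auc_score, labels = y[hold])
  best <- lams[which.max(auc)]
  list(model = path, lambda = best)
}

#' Cross-validated PCA + L1-logistic boundary decoder
#'
#' The generic decoding engine: stratified k-fold cross-validation; within
#' each fold, PCA is fit on the training rows only and truncated at the
#' smallest number of components cumulatively explaining more than
#' `var_frac` of the variance; an L1-regularized logistic regression
#' (penalty chosen on an inner split) is trained on the training-fold
#' component scores; the held-out fold receives posterior scores exactly
#' once. AUC is computed per fold.
#'
#' @param X `events x features` matrix.
#' @param labels event labels (`"word"` positive vs `"within"`).
#' @param folds number of folds (default 20).
#' @param seed integer seed (folds, inner splits).
#' @param var_frac PCA variance fraction (default 0.9).
#' @return object of class `decoder_result`: `fold_auc` (length `folds`),
#'   `auc` (their mean), `scores` (held-out posterior per event),
#'   `labels`, `fold` (assignment), `pc_count` (per fold).
#' @export
decode_core <- function(X, labels, folds = 20, seed = 1, var_frac = 0.9) {
  y <- as.integer(labels == "word" | labels == 1 | labels == TRUE)
  if (length(unique(y)) < 2) stop("need two classes after exclusions")
  fold <- stratified_folds(y, folds, seed)
  scores <- numeric(length(y))
  fold_auc <- numeric(folds)
  pc_count <- integer(folds)
  for (k in seq_len(folds)) {
    te <- fold == k
    pca <- pca_fit(X[!te, , drop = FALSE], var_frac)
    pc_count[k] <- pca$k
    Ztr <- pca_project(pca, X[!te, , drop = FALSE])
    Zte <- pca_project(pca, X[te, , drop = FALSE])
    m <- l1_logistic(Ztr, y[!te], seed = seed + k)
    sc <- drop(stats::predict(m$model, Zte, s = m$lambda, type = "response"))
    scores[te] <- sc
    fold_auc[k] <- auc_score(sc, y[te])
  }
  structure(list(fold_auc = fold_auc, auc = mean(fold_auc), scores = scores,
                 labels = y, fold = fold, pc_count = pc_count,
                 var_frac = var_frac, seed = seed),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat("<decoder_result> mean AUC ", round(x$auc, 3), " over ",
      length(x$fold_auc), " folds (", round(mean(x$pc_count)),
      " PCs on average)\n", sep = "")
  invisible(x)
}

#' Acoustic word-boundary decoding
#'
#' Classifies word versus within-word syllable boundaries from the
#' vectorized 0.2 s, 80-band mel-spectrogram window around each event,
#' via [decode_core()].
#'
#' @param sentences rendered sentences.
#' @param events events to decode (pre-sampled, non-excluded).
#' @param half window half-width in frames (default 10 = 0.1 s).
#' @param folds,seed,var_frac passed to [decode_core()].
#' @return a `decoder_result`; the retained events are in `$events`.
#' @export
acoustic_decode <- function(sentences, events, half = 10, folds = 20,
                            seed = 1, var_frac = 0.9) {
  w <- event_windows_mel(sentences, events, half)
  res <- decode_core(w$X, w$events$label, folds, seed, var_frac)
  res$events <- w$events
  res
}

#' Cross-language transfer decoding
#'
#' Fits PCA and the L1-logistic decoder on all events of the training
#' language and applies them unchanged to the test language's events.
#'
#' @param X_train,labels_train training windows and labels.
#' @param X_test,labels_test test windows and labels (same feature layout).
#' @param seed,var_frac as in [decode_core()].
#' @return list: `auc` on the test language, `scores`, `pc_count`.
#' @export
transfer_decode <- function(X_train, labels_train, X_test, labels_test,
                            seed = 1, var_frac = 0.9) {
  if (ncol(X_train) != ncol(X_test))
    stop("window dimensions differ between languages: ", ncol(X_train),
         " vs ", ncol(X_test))
  ytr <- as.integer(labels_train == "word" | labels_train == 1)
  yte <- as.integer(labels_test == "word" | labels_test == 1)
  pca <- pca_fit(X_train, var_frac)
  m <- l1_logistic(pca_project(pca, X_train), ytr, seed = seed)
  sc <- drop(stats::predict(m$model, pca_project(pca, X_test), s = m$lambda,
                            type = "response"))
  list(auc = auc_score(sc, yte), scores = sc, pc_count = pca$k)
}

#' Label-permutation null for a boundary decoder
#'
#' Shuffles the class labels and re-runs the decoding procedure. The fold
#' assignment (stratified on the observed labels) and the per-fold
#' training PCA are computed once and reused across permutations -- labels
#' enter only the logistic stage, so the null is exact while the expensive
#' unsupervised steps are shared.
#'
#' @param X windows matrix.
#' @param labels observed labels.
#' @param n_perms number of label shuffles (default 25).
#' @param folds,seed,var_frac as in [decode_core()].
#' @return list `auc` (`n_perms x folds` matrix of held-out AUCs),
#'   `median_auc` (median over all entries).
#' @export
label_permutation_null <- function(X, labels, n_perms = 25, folds = 20,
                                   seed = 1, var_frac = 0.9) {
  y <- as.integer(labels == "word" | labels == 1 | labels == TRUE)
  fold <- stratified_folds(y, folds, seed)
  fold_pcas <- lapply(seq_len(folds), function(k)
    pca_fit(X[fold != k, , drop = FALSE], var_frac))
  Ztr <- lapply(seq_len(folds), function(k)
    pca_project(fold_pcas[[k]], X[fold != k, , drop = FALSE]))
  Zte <- lapply(seq_len(folds), function(k)
    pca_project(fold_pcas[[k]], X[fold == k, , drop = FALSE]))
  local_rng(seed + 17L)
  aucs <- matrix(0, n_perms, folds)
  for (pmi in seq_len(n_perms)) {
    yp <- sample(y)
    for (k in seq_len(folds)) {
      te <- fold == k
      m <- l1_logistic(Ztr[[k]], yp[!te],
                       seed = seed + 1000L * pmi + k)
      sc <- drop(stats::predict(m$model, Zte[[k]], s = m$lambda,
                                type = "response"))
      aucs[pmi, k] <- auc_score(sc, yp[te])
    }
  }
  list(auc = aucs, median_auc = stats::median(aucs))
}

#' Neural discrimination of boundary type per electrode
#'
#' For each electrode, tests at every frame of the `(-0.2, +0.4)` s
#' event-aligned window whether the HFA differs between word and
#' within-word events (two-group one-way ANOVA F-test, Bonferroni over the
#' window's frames at threshold `alpha`). An electrode discriminates
#' boundaries when it shows at least `run_s` (default 50 ms) of contiguous
#' significant frames.
#'
#' @param recording a `neural_recording`.
#' @param events non-excluded events (>= 10 per class).
#' @param pre,post window frames (default 20/40).
#' @param alpha Bonferroni-corrected threshold (default 0.01).
#' @param run_s contiguity requirement in seconds (default 0.05).
#' @return data.frame per electrode: `electrode, discriminates,
#'   longest_run_s`; the per-frame significance masks in
#'   `attr(, "sig_mask")`.
#' @export
neural_boundary_discrimination <- function(recording, events, pre = 20,
                                           post = 40, alpha = 0.01,
                                           run_s = 0.05) {
  w <- event_windows_neural(recording, events, pre, post)
  ev <- w$events
  if (min(table(ev$label)) < 10) stop("need >= 10 events per class")
  y <- ev$label == "word"
  n_e <- w$n_electrodes
  n_t <- w$n_frames
  need <- as.integer(round(run_s * recording$fs))
  sig <- matrix(FALSE, n_e, n_t)
  runs <- numeric(n_e)
  for (e in seq_len(n_e)) {
    M <- w$X[, ((e - 1) * n_t + 1):(e * n_t), drop = FALSE]
    # frame-wise two-group ANOVA F between the two event classes
    m1 <- colMeans(M[y, , drop = FALSE]); m0 <- colMeans(M[!y, , drop = FALSE])
    v1 <- apply(M[y, , drop = FALSE], 2, stats::var)
    v0 <- apply(M[!y, , drop = FALSE], 2, stats::var)
    n1 <- sum(y); n0 <- sum(!y)
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    f <- (m1 - m0)^2 / (sp * (1 / n1 + 1 / n0))
    p <- stats::pf(f, 1, n1 + n0 - 2, lower.tail = FALSE)
    sig[e, ] <- p * n_t < alpha
    runs[e] <- longest_run(sig[e, ])
  }
  out <- data.frame(electrode = seq_len(n_e),
                    discriminates = runs >= need,
                    longest_run_s = runs / recording$fs)
  attr(out, "sig_mask") <- sig
  out
}

#' Neural word-boundary decoding
#'
#' Decodes boundary type from the vectorized electrode x time HFA window
#' around each event ([decode_core()] on [event_windows_neural()]). A
#' single-electrode input is supported (single-participant variant).
#'
#' @param recording a `neural_recording`.
#' @param events non-excluded events.
#' @param pre,post window frames (default 20/40).
#' @param electrodes electrode subset (e.g. the speech-responsive set).
#' @param folds,seed,var_frac passed to [decode_core()].
#' @return a `decoder_result` with `$events`.
#' @export
neural_decode <- function(recording, events, pre = 20, post = 40,
                          electrodes = seq_len(nrow(recording$hfa)),
                          folds = 20, seed = 1, var_frac = 0.9) {
  if (length(electrodes) == 0) stop("no electrodes selected")
  w <- event_windows_neural(recording, events, pre, post, electrodes)
  res <- decode_core(w$X, w$events$label, folds, seed, var_frac)
  res$events <- w$events
  res
}

#' Sliding-window neural decoding time-course
#'
#' Repeats the neural decoding within consecutive non-overlapping windows
#' of `width_s` (default 0.02 s) spanning the 0.6 s event-aligned window,
#' with the same trials, electrodes and fold assignment throughout.
#'
#' @inheritParams neural_decode
#' @param width_s sub-window width in seconds.
#' @return data.frame: `window_start_s, window_end_s, auc`, with the
#'   per-fold AUC matrix in `attr(, "fold_auc")`.
#' @export
sliding_window_decode <- function(recording, events, pre = 20, post = 40,
                                  electrodes = seq_len(nrow(recording$hfa)),
                                  width_s = 0.02, folds = 20, seed = 1,
                                  var_frac = 0.9) {
  wd <- as.integer(round(width_s * recording$fs))
  if (wd < 1) stop("window width below one frame")
  w <- event_windows_neural(recording, events, pre, post, electrodes)
  n_t <- as.integer(w$n_frames)
  n_e <- as.integer(w$n_electrodes)
  starts <- as.integer(seq(1L, n_t - wd + 1L, by = wd))
  y <- as.integer(w$events$label == "word")
  fold <- stratified_folds(y, folds, seed)
  out <- lapply(starts, function(s0) {
    cols <- as.vector(vapply(seq_len(n_e), function(e)
      (e - 1L) * n_t + s0 + 0:(wd - 1L), integer(wd)))
    Xs <- w$X[, cols, drop = FALSE]
    fa <- numeric(folds)
    for (k in seq_len(folds)) {
      te <- fold == k
      pca <- pca_fit(Xs[!te, , drop = FALSE], var_frac)
      m <- l1_logistic(pca_project(pca, Xs[!te, , drop = FALSE]), y[!te],
                       seed = seed + k)
      sc <- drop(stats::predict(m$model, pca_project(pca, Xs[te, , drop = FALSE]),
                                s = m$lambda, type = "response"))
      fa[k] <- auc_score(sc, y[te])
    }
    fa
  })
  fa <- do.call(rbind, out)
  res <- data.frame(window_start_s = (starts - 1 - pre) / recording$fs,
                    window_end_s = (starts - 1 - pre + wd) / recording$fs,
                    auc = rowMeans(fa))
  attr(res, "fold_auc") <- fa
  res
}
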