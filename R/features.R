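#' Names and groupings of the encoding-model features
#'
#' The full predictor set of the feature TRF model: sentence onset, peakRate
#' (acoustic envelope edges), six consonant articulatory-class flags, four
#' vowel formants, and the four word-level/sequence features (word onset,
#' log10 word frequency, word length in phonemes, within-word phoneme
#' surprisal in bits). The first twelve form the acoustic--phonetic model.
#'
#' @return character vector of feature names, in canonical order.
#' @export
feature_names <- function() {
  c("sentence_onset", "peakRate",
    "dorsal", "coronal", "labial", "nasal", "plosive", "fricative",
    "F1", "F2", "F3", "F4",
    "word_onset", "word_frequency", "word_length", "phoneme_surprisal")
}

#' @rdname feature_names
#' @export
acoustic_features <- function() feature_names()[1:12]

#' @rdname feature_names
#' @export
word_level_features <- function() feature_names()[13:16]

# features whose event values are continuous (z-scored at fit time);
# binary impulses are left 0/1
continuous_features <- function() {
  c("peakRate", "F1", "F2", "F3", "F4",
    "word_frequency", "word_length", "phoneme_surprisal")
}

#' Detect peakRate events in an amplitude envelope
#'
#' peakRate events are the acoustic edges of the envelope: local maxima of
#' the positive part of its first difference, with the derivative value as
#' event magnitude.
#'
#' @param envelope non-negative envelope sampled at `fs` Hz.
#' @param fs frame rate (Hz).
#' @return data.frame `time` (s), `frame`, `magnitude`; zero rows for a
#'   constant envelope.
#' @export
detect_peak_rate <- function(envelope, fs = 100) {
  if (any(envelope < 0)) stop("envelope must be non-negative")
  d <- pmax(diff(envelope), 0)
  n <- length(d)
  if (n < 3 || all(d == 0))
    return(data.frame(time = numeric(0), frame = integer(0), magnitude = numeric(0)))
  is_peak <- d > 0 & d >= c(Inf, d[-n]) & d > c(d[-1], Inf)
  idx <- which(is_peak)
  # d[i] = env[i+1]-env[i]: rate peak assigned to frame i+1
  data.frame(time = idx / fs, frame = idx + 1L, magnitude = d[idx])
}

#' Build the feature stream of a sentence
#'
#' Produces the time x feature matrix at 100 Hz consumed by the encoding
#' models. Impulse features are zero except at event frames; events mapping
#' to the same frame are summed. Consonant class flags and formant values
#' are placed at phoneme-onset frames, the sentence-onset impulse at frame
#' one, word-level features at word-onset frames, and phoneme surprisal at
#' non-initial phoneme-onset frames only (word-initial phonemes carry none,
#' so word-level and surprisal features are dissociated in time).
#'
#' @param sentence an `annotated_sentence` with rendered acoustics (the
#'   envelope is needed for peakRate).
#' @param lexicon a `freq_lexicon` covering the sentence's words (missing
#'   words are flagged: word_onset is still emitted, frequency/length are 0
#'   with a warning).
#' @param fs frame rate (Hz).
#' @return matrix `frames x 16` with `colnames = feature_names()`.
#' @export
build_feature_stream <- function(sentence, lexicon, fs = 100) {
  stopifnot(inherits(sentence, "annotated_sentence"),
            inherits(lexicon, "freq_lexicon"))
  if (is.null(sentence$envelope))
    stop("sentence has no rendered envelope; call render_acoustics() first")
  inv <- sentence_inventory(sentence)
  n_frames <- length(sentence$envelope)
  feats <- feature_names()
  X <- matrix(0, n_frames, length(feats), dimnames = list(NULL, feats))

  add <- function(feature, frame, value = 1) {
    ok <- frame >= 1 & frame <= n_frames
    for (i in which(ok)) X[frame[i], feature] <<- X[frame[i], feature] + value[min(i, length(value))]
  }

  X[1, "sentence_onset"] <- 1

  pr <- detect_peak_rate(sentence$envelope, fs)
  if (nrow(pr) > 0) add("peakRate", pr$frame, pr$magnitude)

  ph <- sentence$phones
  pi_ <- match(ph$phoneme, inv$phoneme)
  if (anyNA(pi_))
    stop("phoneme(s) missing class attributes: ",
         paste(unique(ph$phoneme[is.na(pi_)]), collapse = ", "))
  pframe <- time_to_frame(ph$onset, fs)
  for (j in seq_len(nrow(ph))) {
    r <- inv[pi_[j], ]
    if (r$vowel) {
      add("F1", pframe[j], r$F1); add("F2", pframe[j], r$F2)
      add("F3", pframe[j], r$F3); add("F4", pframe[j], r$F4)
    } else {
      for (cl in c("dorsal", "coronal", "labial", "nasal", "plosive", "fricative"))
        if (r[[cl]] == 1) add(cl, pframe[j], 1)
    }
  }

  wframe <- time_to_frame(sentence$words$onset, fs)
  missing_words <- character(0)
  for (j in seq_len(nrow(sentence$words))) {
    w <- sentence$words$word[j]
    add("word_onset", wframe[j], 1)
    wf <- suppressWarnings(word_features(lexicon, w))
    if (is.na(wf$log10_frequency)) {
      missing_words <- c(missing_words, w)
    } else {
      add("word_frequency", wframe[j], wf$log10_frequency)
      add("word_length", wframe[j], wf$length)
    }
    # within-word surprisal at phones 2..n of this word
    wp <- ph[ph$word_index == j, , drop = FALSE]
    phones_w <- wp$phoneme
    if (length(phones_w) >= 2) {
      for (k in 2:length(phones_w)) {
        s <- suppressWarnings(phoneme_surprisal(lexicon, phones_w[seq_len(k)]))
        if (!is.na(s)) add("phoneme_surprisal", time_to_frame(wp$onset[k], fs), s)
      }
    }
  }
  if (length(missing_words) > 0) {
    warning("words not in lexicon (features omitted): ",
            paste(unique(missing_words), collapse = ", "))
    attr(X, "missing_words") <- unique(missing_words)
  }
  X
}

# T x F -> T x (F * n_lags) lag expansion, feature-major column blocks:
# column (f-1)*L + l + 1 at row t equals x[t - l, f], zero for t - l < 1.
lag_matrix <- function(x, n_lags) {
  if (n_lags < 1) stop("n_lags must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  out <- matrix(0, n, p * n_lags)
  for (f in seq_len(p)) {
    base <- (f - 1L) * n_lags
    for (l in 0:(n_lags - 1L)) {
      if (l < n) out[(l + 1L):n, base + l + 1L] <- x[1:(n - l), f]
    }
  }
  cn <- colnames(x)
  if (!is.null(cn))
    colnames(out) <- paste0(rep(cn, each = n_lags), "_lag", 0:(n_lags - 1L))
  out
}

#' Event-level scaling statistics for feature streams
#'
#' Continuous features (peakRate magnitude, formants, word frequency/length,
#' surprisal) are z-scored at their event frames using statistics estimated
#' from a training set of streams; binary impulses are left 0/1. Returns
#' the statistics so the identical transform can be applied to held-out
#' streams.
#'
#' @param streams list of feature-stream matrices (training set).
#' @return data.frame `feature, mean, sd` for the continuous features.
#' @export
feature_scale_stats <- function(streams) {
  feats <- continuous_features()
  do.call(rbind, lapply(feats, function(f) {
    v <- unlist(lapply(streams, function(s) { x <- s[, f]; x[x != 0] }))
    m <- if (length(v)) mean(v) else 0
    sd_ <- if (length(v) > 1) stats::sd(v) else 1
    if (!is.finite(sd_) || sd_ < 1e-12) sd_ <- 1
    data.frame(feature = f, mean = m, sd = sd_)
  }))
}

#' @rdname feature_scale_stats
#' @param stats result of `feature_scale_stats()` on the training streams.
#' @export
scale_streams <- function(streams, stats) {
  lapply(streams, function(s) {
    for (i in seq_len(nrow(stats))) {
      f <- stats$feature[i]
      nz <- s[, f] != 0
      s[nz, f] <- (s[nz, f] - stats$mean[i]) / stats$sd[i]
    }
    s
  })
}

#' Assemble the lagged design matrix over sentences
#'
#' Pads each sentence's feature stream with `pre` leading zero frames (the
#' silent prestimulus baseline) and `post` trailing zero frames (so lagged
#' responses to sentence-final events are represented), lag-expands each
#' sentence independently over `n_lags` lags (0 .. `n_lags`-1 frames; rows
#' whose lag reaches before the sentence start use zeros), and stacks them.
#'
#' @param streams list of feature-stream matrices (one per sentence).
#' @param sentence_ids ids parallel to `streams`.
#' @param n_lags number of lags (default 60, i.e. 0.6 s at 100 Hz).
#' @param pre,post zero-padding frames per sentence (default 50 and 60).
#' @return object of class `lagged_design`: list with `X` (rows x
#'   `16 * n_lags`), `sentence` (row grouping), `features`, `n_lags`.
#' @export
assemble_design <- function(streams, sentence_ids = seq_along(streams),
                            n_lags = 60, pre = 50, post = 60) {
  feats <- colnames(streams[[1]])
  parts <- lapply(streams, function(s) {
    sp <- rbind(matrix(0, pre, ncol(s)), s, matrix(0, post, ncol(s)))
    lag_matrix(sp, n_lags)
  })
  rows <- rep(sentence_ids, vapply(parts, nrow, integer(1)))
  structure(list(X = do.call(rbind, parts), sentence = rows,
                 features = feats, n_lags = n_lags, pre = pre, post = post),
            class = "lagged_design")
}

# column indices of a feature subset in a lagged design
design_cols <- function(design, features) {
  idx <- match(features, design$features)
  if (anyNA(idx))
    stop("features not in design: ",
         paste(features[is.na(idx)], collapse = ", "))
  L <- as.integer(design$n_lags)
  as.vector(vapply(as.integer(idx), function(f)
    (f - 1L) * L + seq_len(L), integer(L)))
}
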