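# Shared fixtures, generated in code at test time.

# Small encoding scenario: one language, rendered stimuli, scaled streams,
# simulated responses for a given ground truth, packed as encoding_data.
make_encoding_scenario <- function(n_electrodes = 4, noise_sd = 1, seed = 1,
                                   n_train = 24, n_test = 6, n_repeats = 2,
                                   condition = "native", truth = NULL,
                                   lang = NULL, ...) {
  lang <- lang %||% make_language(seed, n_words = 48)
  n_all <- n_train + n_test
  sents <- sample_sentences(lang, n_all, seed = seed + 1)
  sents <- lapply(sents, render_acoustics, seed = seed + 2)
  lex <- build_lexicon(lang)
  streams <- lapply(sents, build_feature_stream, lexicon = lex)
  names(streams) <- seq_len(n_all)
  streams <- scale_streams(streams, feature_scale_stats(streams[1:n_train]))
  truth <- truth %||% make_ground_truth_trf(n_electrodes, seed = seed + 3,
                                            noise_sd = noise_sd, ...)
  test_ids <- seq(n_train + 1L, n_all)
  trials <- data.frame(
    trial = seq_len(n_train + n_test * n_repeats),
    sentence = c(seq_len(n_train), rep(test_ids, each = n_repeats)))
  rec <- simulate_neural(streams, trials, truth, condition, seed = seed + 4)
  al <- rec$alignment
  Ytr <- do.call(rbind, lapply(seq_len(n_train), function(i) {
    a <- al[al$trial == i, ]
    t(rec$hfa[, a$start:a$end, drop = FALSE])
  }))
  Yte <- do.call(rbind, lapply(test_ids, function(s) {
    aa <- al[al$sentence == s, , drop = FALSE]
    reps <- lapply(seq_len(nrow(aa)), function(i)
      t(rec$hfa[, aa$start[i]:aa$end[i], drop = FALSE]))
    Reduce(`+`, reps) / length(reps)
  }))
  ed <- build_encoding_data(streams[seq_len(n_train)], Ytr,
                            streams[test_ids], Yte)
  list(ed = ed, truth = truth, lang = lang, lexicon = lex,
       sentences = sents, streams = streams, recording = rec)
}

# Boundary-decoding scenario: rendered sentences + sampled balanced events.
make_boundary_scenario <- function(n_sentences = 60, ambiguity = 0,
                                   n_per_class = 200, seed = 1,
                                   lang = NULL) {
  lang <- lang %||% make_language(seed)
  sents <- sample_sentences(lang, n_sentences, seed = seed + 1)
  sents <- lapply(sents, render_acoustics, ambiguity_fraction = ambiguity,
                  seed = seed + 2)
  ev <- extract_events(sents)
  n <- min(n_per_class, min(table(ev$label[!ev$excluded])))
  list(sentences = sents, events = sample_events(ev, n, n, seed = seed + 3),
       all_events = ev, lang = lang)
}

# brute-force surprisal oracle: enumerate the word table directly
oracle_surprisal <- function(words, counts, prefix) {
  freq <- function(pf) {
    hit <- vapply(words, function(w) {
      ph <- strsplit(w, " ", fixed = TRUE)[[1]]
      length(ph) >= length(pf) && all(ph[seq_along(pf)] == pf)
    }, logical(1))
    sum(counts[hit])
  }
  n <- length(prefix)
  -log2(freq(prefix) / freq(prefix[-n]))
}
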