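#' Sample annotated sentences from a synthetic language
#'
#' Draws words proportional to lexicon token counts and assigns phone
#' durations from a log-normal model (median `dur_median` s, log-sd
#' `dur_sdlog`), yielding time-aligned phoneme, syllable and word tiers.
#' A configurable fraction of sentences is marked with a `repeat_group`
#' identifier: these play the role of the held-out test sentences that are
#' presented repeatedly and averaged when evaluating encoding models.
#'
#' @param language a `synth_language`.
#' @param n_sentences number of sentences.
#' @param words_range integer length-2: inclusive range of words/sentence.
#' @param seed integer seed; output is deterministic in `(language, args)`.
#' @param repeat_fraction fraction of sentences marked as repeat/test items.
#' @param dur_median,dur_sdlog phone-duration log-normal parameters
#'   (seconds; defaults 0.08 and 0.3, natural speech scale).
#' @return list of `annotated_sentence` objects: each has `id`, `language`,
#'   `duration` (s), `words` (data.frame `word,onset,offset,n_syllables`),
#'   `phones` (data.frame `phoneme,onset,offset,word_index,syllable_index`),
#'   `syllable_onsets` (s), `repeat_group` (`NA` or group id).
#' @export
sample_sentences <- function(language, n_sentences, words_range = c(5, 9),
                             seed = 1, repeat_fraction = 0,
                             dur_median = 0.08, dur_sdlog = 0.3) {
  stopifnot(inherits(language, "synth_language"))
  local_rng(seed)
  lex <- language$lexicon
  probs <- lex$count / sum(lex$count)
  lang_id <- paste0("L", language$seed)

  n_rep <- round(repeat_fraction * n_sentences)
  rep_ids <- if (n_rep > 0) sample.int(n_sentences, n_rep) else integer(0)

  lapply(seq_len(n_sentences), function(si) {
    nw <- sample(seq(words_range[1], words_range[2]), 1)
    wi <- sample.int(nrow(lex), nw, replace = TRUE, prob = probs)
    t0 <- 0
    words <- list(); phones <- list(); syl_on <- numeric(0)
    for (j in seq_along(wi)) {
      sy <- strsplit(lex$syllables[wi[j]], " . ", fixed = TRUE)[[1]]
      w_on <- t0
      for (k in seq_along(sy)) {
        ph <- strsplit(sy[k], " ", fixed = TRUE)[[1]]
        syl_on <- c(syl_on, t0)
        for (p in ph) {
          d <- stats::rlnorm(1, meanlog = log(dur_median), sdlog = dur_sdlog)
          while (d <= 0) d <- stats::rlnorm(1, log(dur_median), dur_sdlog)
          phones[[length(phones) + 1L]] <- data.frame(
            phoneme = p, onset = t0, offset = t0 + d,
            word_index = j, syllable_index = length(syl_on))
          t0 <- t0 + d
        }
      }
      words[[j]] <- data.frame(word = lex$word[wi[j]], onset = w_on,
                               offset = t0, n_syllables = length(sy))
    }
    structure(list(
      id = si, language = lang_id, duration = t0,
      words = do.call(rbind, words), phones = do.call(rbind, phones),
      syllable_onsets = syl_on,
      repeat_group = if (si %in% rep_ids) paste0(lang_id, "_rep", si) else NA_character_
    ), class = "annotated_sentence", inventory = language$inventory)
  })
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence> id=", x$id, " lang=", x$language,
      " dur=", round(x$duration, 2), "s words=", nrow(x$words),
      " syllables=", length(x$syllable_onsets),
      if (!is.na(x$repeat_group)) paste0(" repeat_group=", x$repeat_group),
      "\n", sep = "")
  invisible(x)
}

# map Hz to one of n mel-spaced bands up to fmax
hz_to_band <- function(f, n_bands = 80, fmax = 8000) {
  mel <- function(h) 2595 * log10(1 + h / 700)
  pmin(n_bands, pmax(1L, ceiling(n_bands * mel(f) / mel(fmax))))
}

# per-phoneme 80-band spectral templates from articulatory classes/formants;
# `contrast` scales the class-specific structure relative to the broadband
# floor that carries the envelope cue
phone_templates <- function(inventory, n_bands = 80, floor = 0.5,
                            contrast = 0.08) {
  bands <- seq_len(n_bands)
  g <- function(center, width, gain = 1)
    contrast * gain * exp(-(bands - center)^2 / (2 * width^2))
  tm <- matrix(floor, n_bands, nrow(inventory),
               dimnames = list(NULL, inventory$phoneme))
  for (i in seq_len(nrow(inventory))) {
    r <- inventory[i, ]
    if (r$vowel) {
      fb <- hz_to_band(c(r$F1, r$F2, r$F3, r$F4), n_bands)
      tm[, i] <- tm[, i] + g(fb[1], 4, 1.2) + g(fb[2], 4, 1.0) +
        g(fb[3], 4, 0.7) + g(fb[4], 4, 0.5)
    } else {
      if (r$labial)    tm[, i] <- tm[, i] + g(12, 8, 0.8)
      if (r$coronal)   tm[, i] <- tm[, i] + g(50, 9, 0.8)
      if (r$dorsal)    tm[, i] <- tm[, i] + g(32, 9, 0.8)
      if (r$nasal)     tm[, i] <- tm[, i] + g(8, 5, 0.9)
      if (r$plosive)   tm[, i] <- tm[, i] + contrast * 0.25 # broadband burst
      if (r$fricative) tm[, i] <- tm[, i] + g(68, 10, 0.9)
    }
  }
  tm
}

#' Render envelope and mel-spectrogram for a sentence
#'
#' Synthesizes a 100 Hz amplitude envelope as per-syllable rise--fall pulses:
#' the envelope reaches a local minimum ("dip") exactly at each syllable
#' onset and a local peak shortly after. Dip depth is the acoustic cue to
#' boundary type: word onsets draw a deep dip (default Normal(0.12, 0.05)),
#' within-word syllable onsets a shallow one (Normal(0.50, 0.08)). For a
#' fraction `ambiguity_fraction` of word boundaries the dip is resampled
#' from the within-word distribution, producing acoustically ambiguous word
#' boundaries that an envelope-based classifier cannot separate. The 80-band
#' mel-spectrogram is the envelope times a noisy phone-class-dependent
#' spectral template.
#'
#' @param sentence an `annotated_sentence`.
#' @param ambiguity_fraction fraction of word boundaries rendered with
#'   within-word dip statistics, in `[0, 1]`.
#' @param seed integer seed.
#' @param fs frame rate (Hz).
#' @param dip_word,dip_within `c(mean, sd)` of the dip-depth normals.
#' @param mel_noise_sd multiplicative log-normal noise sd on mel bands.
#' @param render_audio also synthesize a 16 kHz noise-carrier waveform.
#' @return the sentence with `envelope` (length `round(duration*fs)`),
#'   `mel` (`n_bands x frames`), `boundaries` (data.frame per syllable
#'   onset: `time, frame, is_word, ambiguous, dip`), and optionally `audio`.
#' @export
render_acoustics <- function(sentence, ambiguity_fraction = 0, seed = 1,
                             fs = 100, dip_word = c(0.12, 0.05),
                             dip_within = c(0.50, 0.08), mel_noise_sd = 0.8,
                             render_audio = FALSE) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  if (ambiguity_fraction < 0 || ambiguity_fraction > 1)
    stop("ambiguity_fraction must be in [0, 1]")
  if (is.null(sentence$phones)) stop("sentence has no phone intervals")
  local_rng(seed + sentence$id * 7919L)

  n_frames <- round(sentence$duration * fs)
  syl_on <- sentence$syllable_onsets
  syl_frames <- time_to_frame(syl_on, fs)
  word_frames <- time_to_frame(sentence$words$onset, fs)
  is_word <- syl_frames %in% word_frames
  n_syl <- length(syl_on)

  # dip depth at each syllable onset
  rnorm_clip <- function(n, ms) pmin(0.9, pmax(0.02, stats::rnorm(n, ms[1], ms[2])))
  dip <- numeric(n_syl)
  ambiguous <- logical(n_syl)
  for (i in seq_len(n_syl)) {
    if (i == 1) { dip[i] <- 0.03; next }
    if (is_word[i]) {
      ambiguous[i] <- stats::runif(1) < ambiguity_fraction
      dip[i] <- if (ambiguous[i]) rnorm_clip(1, dip_within) else rnorm_clip(1, dip_word)
    } else {
      dip[i] <- rnorm_clip(1, dip_within)
    }
  }
  amp <- pmax(0.6, stats::rnorm(n_syl, 1, 0.08))

  env <- numeric(n_frames)
  ends <- c(syl_frames[-1] - 1L, n_frames)
  inter_level <- 0.55
  for (i in seq_len(n_syl)) {
    f0 <- syl_frames[i]; f1 <- max(ends[i], f0)
    len <- f1 - f0 + 1L
    tau <- if (len > 1) (seq_len(len) - 1) / (len - 1) else 0
    tp <- 0.4
    endv <- if (i == n_syl) 0.02 else inter_level
    seg <- ifelse(tau <= tp,
                  dip[i] + (amp[i] - dip[i]) * sin(pi / 2 * tau / tp)^2,
                  endv + (amp[i] - endv) * cos(pi / 2 * (tau - tp) / (1 - tp))^2)
    env[f0:f1] <- seg
  }

  # mel: envelope x phone template, multiplicative log-normal noise
  tmpl <- phone_templates(sentence_inventory(sentence), n_bands = 80)
  ph_idx <- findInterval((seq_len(n_frames) - 0.5) / fs, sentence$phones$onset)
  ph_idx[ph_idx < 1] <- 1L
  ph_name <- sentence$phones$phoneme[ph_idx]
  mel <- tmpl[, ph_name, drop = FALSE] *
    matrix(env, 80, n_frames, byrow = TRUE) *
    exp(matrix(stats::rnorm(80 * n_frames, 0, mel_noise_sd), 80, n_frames))
  dimnames(mel) <- NULL

  sentence$envelope <- env
  sentence$mel <- mel
  sentence$fs_frame <- fs
  sentence$boundaries <- data.frame(
    time = syl_on, frame = syl_frames, is_word = is_word,
    ambiguous = ambiguous, dip = dip)
  if (render_audio) {
    up <- rep(env, each = 160)
    sentence$audio <- list(samples = up * stats::rnorm(length(up)), fs = 16000)
  }
  sentence
}

# inventory lookup for a sentence: templates need class flags + formants;
# the default inventory covers the default generator.
sentence_inventory <- function(sentence) {
  inv <- attr(sentence, "inventory") %||% default_inventory()
  missing <- setdiff(unique(sentence$phones$phoneme), inv$phoneme)
  if (length(missing) > 0)
    stop("phoneme(s) missing from inventory: ", paste(missing, collapse = ", "))
  inv
}

#' Measure the pre-boundary envelope dip
#'
#' Minimum envelope value in the 4 frames up to and including the boundary
#' frame; the quantity the generator controls and the acoustic decoder
#' exploits.
#' @param envelope numeric envelope at 100 Hz.
#' @param frame boundary frame (1-based).
#' @return minimum envelope value near the boundary.
#' @export
boundary_dip <- function(envelope, frame) {
  lo <- max(1L, frame - 3L); hi <- min(length(envelope), frame + 1L)
  min(envelope[lo:hi])
}
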