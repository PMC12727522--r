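#' Default phoneme inventory
#'
#' A small cross-linguistically plausible inventory: 12 consonants carrying
#' the six binary articulatory-class features used by the encoding models
#' (dorsal, coronal, labial, nasal, plosive, fricative) and 5 vowels with
#' canonical median formant values F1--F4 in Hz. Two synthetic languages
#' share this inventory but differ in their lexicons.
#'
#' @return A data.frame with one row per phoneme: `phoneme`, `vowel`,
#'   the six consonant-class flags, and `F1`..`F4` (Hz, `NA` for consonants).
#' @export
default_inventory <- function() {
  # includes liquid/glide consonants (l, w) with place but no
  # nasal/plosive/fricative manner, so the six class columns are linearly
  # independent of the bare consonant-onset indicator
  cons <- data.frame(
    phoneme   = c("p", "b", "t", "d", "k", "g", "m", "n", "s", "f", "x", "z",
                  "l", "w"),
    vowel     = FALSE,
    dorsal    = c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 0, 0, 1),
    coronal   = c(0, 0, 1, 1, 0, 0, 0, 1, 1, 0, 0, 1, 1, 0),
    labial    = c(1, 1, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1),
    nasal     = c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    plosive   = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    fricative = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0),
    F1 = NA_real_, F2 = NA_real_, F3 = NA_real_, F4 = NA_real_
  )
  vow <- data.frame(
    phoneme = c("a", "e", "i", "o", "u"),
    vowel   = TRUE,
    dorsal = 0, coronal = 0, labial = 0, nasal = 0, plosive = 0, fricative = 0,
    F1 = c(700, 500, 300, 450, 350),
    F2 = c(1200, 1800, 2300, 900, 800),
    F3 = c(2600, 2500, 3000, 2400, 2300),
    F4 = c(3400, 3400, 3600, 3300, 3200)
  )
  rbind(cons, vow)
}

#' Generate a synthetic language
#'
#' Builds a toy lexicon of `n_words` words over a shared phoneme inventory.
#' Words are concatenations of 1--3 syllables drawn from a language-specific
#' syllable pool (consonant--vowel cores with optional coda), which makes
#' shared word prefixes common, so within-word phoneme surprisal is
#' non-degenerate. Word token counts follow a Zipf law,
#' `count(rank) = round(c * rank^-zipf_exponent)`, floored at 1 so surprisal
#' stays finite.
#'
#' @param seed integer; the lexicon is a pure function of `(seed, arguments)`.
#' @param n_words number of distinct words (>= 2).
#' @param zipf_exponent Zipf exponent (dimensionless), default 1.
#' @param inventory data.frame as [default_inventory()].
#' @param n_syllable_pool size of the syllable pool words are built from.
#' @param top_count token count of the rank-1 word.
#' @param syllable_count_probs probabilities of a word having 1, 2, 3
#'   syllables.
#' @return An object of class `synth_language`: list with `inventory`,
#'   `lexicon` (data.frame `word`, `phones` (space-separated),
#'   `syllables` (`.`-separated), `count`), `zipf_exponent`, `seed`.
#' @export
make_language <- function(seed, n_words = 48, zipf_exponent = 1,
                          inventory = default_inventory(),
                          n_syllable_pool = 24, top_count = 10000,
                          syllable_count_probs = c(0.25, 0.45, 0.30)) {
  if (nrow(inventory) == 0) stop("empty phoneme inventory")
  if (n_words < 2) stop("n_words must be >= 2")
  rng <- local_rng(seed)
  cons <- inventory$phoneme[!inventory$vowel]
  vows <- inventory$phoneme[inventory$vowel]
  if (length(cons) == 0 || length(vows) == 0)
    stop("inventory must contain consonants and vowels")

  # syllable pool: CV or CVC, sampled without replacement where possible
  pool <- character(0)
  while (length(pool) < n_syllable_pool) {
    syl <- paste(c(sample(cons, 1), sample(vows, 1),
                   if (stats::runif(1) < 0.3) sample(cons, 1)), collapse = " ")
    pool <- union(pool, syl)
  }

  words <- character(0)
  sylls <- character(0)
  while (length(words) < n_words) {
    k <- sample.int(3, 1, prob = syllable_count_probs)
    ss <- sample(pool, k, replace = TRUE)
    w <- paste(ss, collapse = " . ")
    if (!(w %in% sylls)) {
      sylls <- c(sylls, w)
      words <- c(words, paste(unlist(strsplit(ss, " ")), collapse = ""))
    }
  }
  counts <- pmax(1L, as.integer(round(top_count * seq_len(n_words)^(-zipf_exponent))))
  lex <- data.frame(
    word      = make.unique(words, sep = "_"),
    phones    = gsub(" \\. ", " ", sylls),
    syllables = sylls,
    count     = counts,
    stringsAsFactors = FALSE
  )
  structure(list(inventory = inventory, lexicon = lex,
                 zipf_exponent = zipf_exponent, seed = seed),
            class = "synth_language")
}

#' @export
print.synth_language <- function(x, ...) {
  cat("<synth_language> ", nrow(x$lexicon), " words, ",
      nrow(x$inventory), " phonemes, zipf s = ", x$zipf_exponent,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Seed a private RNG stream for the calling function without disturbing the
# caller's RNG state.
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}

#' Build a frequency lexicon with its prefix-frequency table
#'
#' The prefix table maps every phoneme prefix `x1..xk` of every word to the
#' summed token counts of all words beginning with that prefix; the empty
#' prefix carries the total mass. It is the sufficient statistic for
#' within-word phoneme surprisal.
#'
#' @param lexicon data.frame with columns `word`, `phones` (space-separated
#'   phoneme string) and `count` (>= 1), or a `synth_language`.
#' @return Object of class `freq_lexicon`: list with `words` (the input
#'   table), `prefix` (named numeric vector of prefix frequencies, names are
#'   space-separated phoneme prefixes) and `total` (the empty-prefix mass,
#'   equal to the summed word counts).
#' @export
build_lexicon <- function(lexicon) {
  if (inherits(lexicon, "synth_language")) lexicon <- lexicon$lexicon
  stopifnot(all(c("word", "phones", "count") %in% names(lexicon)))
  if (any(lexicon$count < 1)) stop("word counts must be >= 1")
  pf <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(lexicon))) {
    ph <- strsplit(lexicon$phones[i], " ", fixed = TRUE)[[1]]
    cnt <- lexicon$count[i]
    for (k in 0:length(ph)) {
      key <- paste(ph[seq_len(k)], collapse = " ")
      pf[[paste0("p:", key)]] <- (pf[[paste0("p:", key)]] %||% 0) + cnt
    }
  }
  keys <- ls(pf)
  prefix <- vapply(keys, function(k) pf[[k]], numeric(1))
  names(prefix) <- substring(keys, 3L)
  total <- unname(prefix[match("", names(prefix))])
  prefix <- prefix[names(prefix) != ""]
  structure(list(words = lexicon, prefix = prefix, total = total),
            class = "freq_lexicon")
}

# frequency of a (possibly empty) phoneme prefix; empty = total mass
prefix_freq <- function(lex, phones) {
  if (length(phones) == 0) return(lex$total)
  unname(lex$prefix[paste(phones, collapse = " ")])
}

#' Within-word phoneme surprisal
#'
#' Surprisal of the final phoneme of the prefix `x1..xn` given `x1..x(n-1)`:
#' `-log2( freq(x1..xn) / freq(x1..x(n-1)) )` in bits, where `freq` is the
#' summed lexicon token count of all words sharing the prefix. Defined only
#' from the second phoneme of a word onward (word-initial phonemes carry no
#' within-word surprisal). An unseen prefix yields `NA` with a warning,
#' never an infinity.
#'
#' @param lexicon a `freq_lexicon` (see [build_lexicon()]).
#' @param phones character vector: the within-word prefix `x1..xn`, n >= 2.
#' @return Surprisal in bits (>= 0), or `NA_real_` for unseen prefixes.
#' @export
phoneme_surprisal <- function(lexicon, phones) {
  stopifnot(inherits(lexicon, "freq_lexicon"))
  n <- length(phones)
  if (n < 2) stop("surprisal is defined from the second phoneme onward (n >= 2)")
  f_full <- prefix_freq(lexicon, phones)
  f_ctx  <- prefix_freq(lexicon, phones[-n])
  if (is.na(f_ctx) || is.null(f_ctx) || length(f_ctx) == 0 || f_ctx == 0 ||
      is.null(f_full) || length(f_full) == 0 || is.na(f_full)) {
    warning("unseen prefix: ", paste(phones, collapse = " "))
    return(NA_real_)
  }
  -log2(f_full / f_ctx)
}

#' Word-level features from the lexicon
#'
#' @param lexicon a `freq_lexicon`.
#' @param word word string.
#' @return list with `log10_frequency` (log10 of token count) and `length`
#'   (number of phonemes); both `NA` (flagged, not dropped) if the word is
#'   out of lexicon.
#' @export
word_features <- function(lexicon, word) {
  stopifnot(inherits(lexicon, "freq_lexicon"))
  i <- match(word, lexicon$words$word)
  if (is.na(i)) {
    warning("word not in lexicon: ", word)
    return(list(log10_frequency = NA_real_, length = NA_integer_))
  }
  list(log10_frequency = log10(lexicon$words$count[i]),
       length = length(strsplit(lexicon$words$phones[i], " ", fixed = TRUE)[[1]]))
}

#' Write / read a lexicon as TSV (word, phones, count)
#' @param lexicon a `freq_lexicon` or lexicon data.frame.
#' @param path file path.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  if (inherits(lexicon, "freq_lexicon")) lexicon <- lexicon$words
  utils::write.table(lexicon[, c("word", "phones", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  build_lexicon(utils::read.delim(path, stringsAsFactors = FALSE))
}
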