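#' Write and read sentence annotations as tiered CSV
#'
#' Long format with one row per interval and a `tier` column
#' (`phone`/`syllable`/`word`), the CSV equivalent of a three-tier Praat
#' TextGrid export.
#'
#' @param sentences list of `annotated_sentence`.
#' @param path CSV file path.
#' @export
write_annotations_csv <- function(sentences, path) {
  rows <- lapply(sentences, function(s) {
    syl_off <- c(s$syllable_onsets[-1], s$duration)
    rbind(
      data.frame(sentence = s$id, language = s$language, tier = "phone",
                 label = s$phones$phoneme, onset = s$phones$onset,
                 offset = s$phones$offset, index = s$phones$word_index),
      data.frame(sentence = s$id, language = s$language, tier = "syllable",
                 label = paste0("syl", seq_along(s$syllable_onsets)),
                 onset = s$syllable_onsets, offset = syl_off,
                 index = seq_along(s$syllable_onsets)),
      data.frame(sentence = s$id, language = s$language, tier = "word",
                 label = s$words$word, onset = s$words$onset,
                 offset = s$words$offset, index = seq_len(nrow(s$words))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @return `read_annotations_csv` returns a list of `annotated_sentence`
#'   objects (without rendered acoustics).
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$sentence), function(d) {
    ph <- d[d$tier == "phone", ]
    sy <- d[d$tier == "syllable", ]
    wd <- d[d$tier == "word", ]
    ph <- ph[order(ph$onset), ]
    sy <- sy[order(sy$onset), ]
    wd <- wd[order(wd$onset), ]
    syl_index <- findInterval(ph$onset + 1e-9, sy$onset)
    n_syl <- vapply(seq_len(nrow(wd)), function(j)
      sum(sy$onset >= wd$onset[j] - 1e-9 & sy$onset < wd$offset[j] - 1e-9),
      numeric(1))
    structure(list(
      id = d$sentence[1], language = d$language[1],
      duration = max(wd$offset),
      words = data.frame(word = wd$label, onset = wd$onset,
                         offset = wd$offset, n_syllables = n_syl),
      phones = data.frame(phoneme = ph$label, onset = ph$onset,
                          offset = ph$offset, word_index = ph$index,
                          syllable_index = syl_index),
      syllable_onsets = sy$onset, repeat_group = NA_character_),
      class = "annotated_sentence")
  })
}

#' Write a neural recording as a plain-text container
#'
#' A directory holding `hfa.csv` (electrodes x frames), `alignment.csv`,
#' `electrodes.csv` and `meta.json` (sampling rate), all plain text.
#'
#' @param recording a `neural_recording`.
#' @param dir output directory (created).
#' @export
write_recording_csv <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(recording$hfa, file.path(dir, "hfa.csv"), row.names = FALSE)
  if (!is.null(recording$alignment))
    utils::write.csv(recording$alignment, file.path(dir, "alignment.csv"),
                     row.names = FALSE)
  if (!is.null(recording$electrodes))
    utils::write.csv(recording$electrodes, file.path(dir, "electrodes.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(fs = recording$fs), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(dir) {
  hfa <- as.matrix(utils::read.csv(file.path(dir, "hfa.csv")))
  dimnames(hfa) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  al <- if (file.exists(file.path(dir, "alignment.csv")))
    utils::read.csv(file.path(dir, "alignment.csv")) else NULL
  el <- if (file.exists(file.path(dir, "electrodes.csv")))
    utils::read.csv(file.path(dir, "electrodes.csv")) else NULL
  structure(list(hfa = hfa, fs = meta$fs, alignment = al, electrodes = el),
            class = "neural_recording")
}

#' Write boundary events as TSV
#' @param events events data.frame.
#' @param path TSV path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
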