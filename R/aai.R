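#' Acoustic ambiguity index (AAI) per boundary event
#'
#' `AAI = |correct label - held-out posterior score|` from the acoustic
#' word-boundary decoder: a continuous per-trial measure of how well
#' acoustic cues support the boundary classification. Large values mark
#' boundaries whose acoustics point the decoder the wrong way.
#'
#' @param decoder a `decoder_result` from [acoustic_decode()] (every event
#'   must carry a held-out posterior score).
#' @return data.frame: `event_id, label, score, aai`.
#' @export
compute_aai <- function(decoder) {
  stopifnot(inherits(decoder, "decoder_result"))
  if (any(!is.finite(decoder$scores))) {
    bad <- which(!is.finite(decoder$scores))
    stop("missing posterior score for event(s): ",
         paste(utils::head(decoder$events$event_id[bad], 5), collapse = ", "))
  }
  data.frame(
    event_id = decoder$events$event_id %||% seq_along(decoder$scores),
    label = decoder$labels,
    score = decoder$scores,
    aai = abs(decoder$labels - decoder$scores))
}

#' Bin AAI values into equal-count tertiles
#'
#' @param records data.frame from [compute_aai()].
#' @param n_bins number of bins (default 3).
#' @return the records with a `bin` factor (`low < mid < high` for 3 bins);
#'   equal counts up to remainder, ties broken by event id for determinism.
#' @export
bin_aai <- function(records, n_bins = 3) {
  if (length(unique(records$aai)) < n_bins)
    stop("fewer than ", n_bins, " distinct AAI values; cannot bin")
  ord <- order(records$aai, records$event_id)
  sizes <- rep(nrow(records) %/% n_bins, n_bins)
  extra <- nrow(records) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab <- if (n_bins == 3) c("low", "mid", "high") else paste0("bin", seq_len(n_bins))
  records$bin <- factor(NA, levels = lab)
  records$bin[ord] <- factor(rep(lab, sizes), levels = lab)
  records
}

#' Native-versus-foreign decoding contrast stratified by AAI bin
#'
#' Within each AAI bin, resamples a fraction of the bin's events
#' (stratified by label, without replacement) `resamples` times per
#' condition, computes the AUC of the native and the foreign neural
#' decoder's held-out scores on each resample, and forms all pairwise
#' native-minus-foreign AUC differences (`resamples^2` values per bin,
#' 225 at the default 15). Bin dependence of the differences is tested
#' with a one-way ANOVA across bins.
#'
#' @param native_scores,foreign_scores held-out posterior scores of the two
#'   neural decoders, aligned to `records` rows (same events).
#' @param records binned AAI records from [bin_aai()].
#' @param resamples resampled AUCs per condition per bin (default 15).
#' @param sample_frac fraction of bin events per resample (default 0.8,
#'   without replacement).
#' @param seed integer seed.
#' @return list: `per_bin` (data.frame `bin, mean_diff, sd_diff`), `diffs`
#'   (long data.frame `bin, diff`), `anova` (`F, df1, df2, p`).
#' @export
bin_auc_contrast <- function(native_scores, foreign_scores, records,
                             resamples = 15, sample_frac = 0.8, seed = 1) {
  stopifnot(length(native_scores) == nrow(records),
            length(foreign_scores) == nrow(records))
  local_rng(seed)
  bins <- levels(records$bin)
  diffs <- lapply(bins, function(b) {
    i <- which(records$bin == b)
    y <- records$label[i]
    if (length(unique(y)) < 2)
      stop("bin ", b, " contains one class only; cannot resample AUC")
    draw <- function(scores) vapply(seq_len(resamples), function(k) {
      idx <- unlist(lapply(unique(y), function(cl) {
        j <- i[y == cl]
        size <- min(length(j), max(2L, round(sample_frac * length(j))))
        j[sample.int(length(j), size)]
      }))
      auc_score(scores[idx], records$label[idx])
    }, numeric(1))
    a_n <- draw(native_scores)
    a_f <- draw(foreign_scores)
    data.frame(bin = b, diff = as.vector(outer(a_n, a_f, "-")))
  })
  diffs <- do.call(rbind, diffs)
  diffs$bin <- factor(diffs$bin, levels = bins)
  av <- stats::anova(stats::lm(diff ~ bin, data = diffs))
  per_bin <- do.call(rbind, lapply(bins, function(b)
    data.frame(bin = b, mean_diff = mean(diffs$diff[diffs$bin == b]),
               sd_diff = stats::sd(diffs$diff[diffs$bin == b]))))
  list(per_bin = per_bin, diffs = diffs,
       anova = data.frame(F = av$`F value`[1], df1 = av$Df[1],
                          df2 = av$Df[2], p = av$`Pr(>F)`[1]))
}
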