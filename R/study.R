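#' Configuration for a simulated bilingual listening study
#'
#' Defaults define the reference simulation: two toy languages sharing one
#' phoneme inventory, four participants (half native in each language, so
#' every participant hears one native and one foreign condition), eight
#' electrodes per participant, 40 training sentences plus 8 held-out test
#' sentences presented 5 times each, observation noise of 1 s.d., and 15%
#' acoustically ambiguous word boundaries.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return named list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_participants = 4,
    electrodes_per_participant = 8,
    n_words = 48,
    zipf_exponent = 1,
    n_train_sentences = 40,
    n_test_sentences = 8,
    n_repeats = 5,
    words_range = c(5, 9),
    noise_sd = 1,
    ambiguity_fraction = 0.15,
    mel_noise_sd = 0.8,
    n_lags = 60, pre = 50, post = 60,
    lambda_grid = 10^seq(-2, 6, length.out = 10),
    cv_folds = 5,
    proficiency = NULL,     # optional per-participant word-feature gain
    truth_args = list()     # extra arguments to make_ground_truth_trf()
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "study_config")
}

# simulate one language's stimulus set: sentences, acoustics, scaled streams
simulate_stimuli <- function(lang, cfg, seed) {
  n_all <- cfg$n_train_sentences + cfg$n_test_sentences
  sents <- sample_sentences(lang, n_all, cfg$words_range, seed = seed)
  sents <- lapply(sents, render_acoustics, ambiguity_fraction =
                    cfg$ambiguity_fraction, seed = seed + 1L,
                  mel_noise_sd = cfg$mel_noise_sd)
  test_ids <- seq(cfg$n_train_sentences + 1L, n_all)
  for (i in test_ids)
    sents[[i]]$repeat_group <- paste0(sents[[i]]$language, "_rep", i)
  lex <- build_lexicon(lang)
  streams <- lapply(sents, build_feature_stream, lexicon = lex)
  names(streams) <- vapply(sents, function(s) as.character(s$id), character(1))
  stats <- feature_scale_stats(streams[seq_len(cfg$n_train_sentences)])
  streams <- scale_streams(streams, stats)
  trials <- data.frame(
    trial = seq_len(cfg$n_train_sentences + cfg$n_test_sentences * cfg$n_repeats),
    sentence = c(seq_len(cfg$n_train_sentences),
                 rep(test_ids, each = cfg$n_repeats)))
  list(sentences = sents, lexicon = lex, streams = streams,
       scale_stats = stats, trials = trials,
       train_ids = seq_len(cfg$n_train_sentences), test_ids = test_ids)
}

# training-row and repeat-averaged test responses aligned to the designs
split_responses <- function(recording, stim) {
  al <- recording$alignment
  tr_rows <- unlist(lapply(stim$train_ids, function(s) {
    a <- al[al$sentence == s, ][1, ]
    a$start:a$end
  }))
  Ytr <- t(recording$hfa[, tr_rows, drop = FALSE])
  Yte <- do.call(rbind, lapply(stim$test_ids, function(s) {
    aa <- al[al$sentence == s, , drop = FALSE]
    reps <- lapply(seq_len(nrow(aa)), function(i)
      t(recording$hfa[, aa$start[i]:aa$end[i], drop = FALSE]))
    Reduce(`+`, reps) / length(reps)
  }))
  list(Ytr = Ytr, Yte = Yte)
}

#' Simulate a full bilingual listening study
#'
#' Generates two languages (shared inventory, disjoint lexicons), their
#' stimulus sets, ground-truth TRFs per participant, and every
#' participant's neural recording for both languages. A participant's
#' condition for a language is `"native"` when it is their native language
#' (word-level feature weights active, scaled by their proficiency) and
#' `"foreign"` otherwise (word-level weights exactly zero); the
#' acoustic--phonetic weights are identical across conditions.
#'
#' @param config a [study_config()].
#' @param seed master seed; all stage seeds are derived from it.
#' @return object of class `speech_study`: `config`, `languages` (named
#'   `A`/`B`), `stimuli` (per language, see internals), `participants`
#'   (data.frame), `electrode_meta` (one row per global electrode),
#'   `truths` (per participant), `recordings` (`recordings[[participant]]
#'   [[language]]`), and `encoding` (per-language [build_encoding_data()]
#'   objects whose response columns stack all participants' electrodes).
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  local_rng(seed)
  seeds <- sample.int(1e8, 64)
  cfg <- config
  langs <- list(A = make_language(seeds[1], cfg$n_words, cfg$zipf_exponent),
                B = make_language(seeds[2], cfg$n_words, cfg$zipf_exponent))
  stim <- list(A = simulate_stimuli(langs$A, cfg, seeds[3]),
               B = simulate_stimuli(langs$B, cfg, seeds[4]))

  n_p <- cfg$n_participants
  prof <- cfg$proficiency %||% rep(1, n_p)
  if (length(prof) != n_p) stop("proficiency must have one value per participant")
  participants <- data.frame(
    participant = paste0("P", seq_len(n_p)),
    native_language = rep(c("A", "B"), length.out = n_p),
    proficiency = prof)

  e_per <- cfg$electrodes_per_participant
  truths <- lapply(seq_len(n_p), function(i)
    do.call(make_ground_truth_trf,
            c(list(e_per, seed = seeds[8] + i, noise_sd = cfg$noise_sd,
                   n_lags = cfg$n_lags, word_gain = prof[i]),
              cfg$truth_args)))
  local_rng(seeds[5])
  electrode_meta <- do.call(rbind, lapply(seq_len(n_p), function(i)
    data.frame(electrode = (i - 1L) * e_per + seq_len(e_per),
               within = seq_len(e_per),
               participant = participants$participant[i],
               hemisphere = sample(c("left", "right"), e_per, replace = TRUE),
               native_language = participants$native_language[i],
               proficiency = prof[i])))

  recordings <- lapply(seq_len(n_p), function(i) {
    out <- lapply(names(langs), function(L) {
      cond <- if (participants$native_language[i] == L) "native" else "foreign"
      rec <- simulate_neural(stim[[L]]$streams, stim[[L]]$trials, truths[[i]],
                             condition = cond,
                             seed = seeds[16] + 101L * i + match(L, names(langs)),
                             pre = cfg$pre, post = cfg$post)
      rec$condition <- cond
      rec$language <- L
      rec$electrodes$participant <- participants$participant[i]
      rec
    })
    stats::setNames(out, names(langs))
  })
  names(recordings) <- participants$participant

  encoding <- lapply(names(langs), function(L) {
    resp <- lapply(seq_len(n_p), function(i)
      split_responses(recordings[[i]][[L]], stim[[L]]))
    Ytr <- do.call(cbind, lapply(resp, `[[`, "Ytr"))
    Yte <- do.call(cbind, lapply(resp, `[[`, "Yte"))
    ed <- build_encoding_data(
      stim[[L]]$streams[stim[[L]]$train_ids], Ytr,
      stim[[L]]$streams[stim[[L]]$test_ids], Yte,
      n_lags = cfg$n_lags, pre = cfg$pre, post = cfg$post)
    meta <- electrode_meta
    meta$condition <- ifelse(meta$native_language == L, "native", "foreign")
    ed$electrode_meta <- meta
    ed
  })
  names(encoding) <- names(langs)

  structure(list(config = cfg, seed = seed, languages = langs, stimuli = stim,
                 participants = participants, electrode_meta = electrode_meta,
                 truths = truths, recordings = recordings,
                 encoding = encoding),
            class = "speech_study")
}

#' @export
print.speech_study <- function(x, ...) {
  cat("<speech_study> ", nrow(x$participants), " participants x 2 languages, ",
      nrow(x$electrode_meta), " electrodes, ",
      x$config$n_train_sentences, "+", x$config$n_test_sentences,
      " sentences/language\n", sep = "")
  invisible(x)
}

#' Unique-variance tables for both languages with condition metadata
#'
#' Runs [variance_partition()] on each language's encoding data and
#' annotates every electrode row with participant, hemisphere, condition
#' (native/foreign) and speaker (stimulus) language, ready for the
#' mixed-model contrast.
#'
#' @param study a `speech_study`.
#' @param schemes scheme table (default [family_schemes()]).
#' @param n_perms permutations per family (0 = none).
#' @param seed fold seed.
#' @return data.frame across both languages.
#' @export
study_variance_partition <- function(study, schemes = family_schemes(),
                                     n_perms = 0, seed = 1) {
  out <- lapply(names(study$encoding), function(L) {
    ed <- study$encoding[[L]]
    vp <- variance_partition(ed, schemes, n_perms,
                             lambda_grid = study$config$lambda_grid,
                             cv_folds = study$config$cv_folds, seed = seed)
    meta <- ed$electrode_meta
    cbind(vp, meta[match(vp$electrode, meta$electrode),
                   c("participant", "hemisphere", "condition", "proficiency")],
          speaker_language = L)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

lme_formula_string <-
  "delta_r2 ~ condition + speaker_language + (1|hemisphere) + (1|participant) + (1|electrode:participant)"

#' Mixed-model condition effect on unique variance
#'
#' For each feature family, fits the linear mixed-effects model
#' `delta_r2 ~ condition + speaker_language + (1|hemisphere) +
#' (1|participant) + (1|electrode:participant)` across electrodes and
#' languages and reports the speech-condition coefficient (positive =
#' native > foreign; `foreign` is the reference level). Random-effect
#' terms whose grouping factor has a single level are dropped with a
#' warning; the formula actually used is stored alongside the estimates.
#'
#' @param partition table from [study_variance_partition()].
#' @param families families to test (default: all present).
#' @return data.frame: `family, estimate, se, t, df, p, n, formula`.
#' @export
lme_condition_effect <- function(partition, families = unique(partition$family)) {
  out <- lapply(families, function(fam) {
    d <- partition[partition$family == fam, ]
    d$condition <- factor(d$condition, levels = c("foreign", "native"))
    d$electrode_in <- paste0(d$participant, "_", d$electrode)
    form <- lme_formula_string
    terms_re <- c(hemisphere = "(1|hemisphere)", participant = "(1|participant)")
    for (v in names(terms_re)) {
      if (length(unique(d[[v]])) < 2) {
        warning("dropping random term for single-level factor: ", v)
        form <- sub(paste0(" \\+ \\Q", terms_re[v], "\\E"), "", form)
      }
    }
    if (length(unique(d$speaker_language)) < 2) {
      warning("dropping fixed effect for single-level speaker_language")
      form <- sub(" \\+ speaker_language", "", form)
    }
    fitted_form <- gsub("electrode:participant", "electrode_in", form)
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(fitted_form), data = d,
                     control = lme4::lmerControl(check.conv.singular =
                                                   lme4::.makeCC(action = "ignore", tol = 1e-4)))))
    co <- summary(fit)$coefficients
    row <- co["conditionnative", ]
    data.frame(family = fam, estimate = row[["Estimate"]],
               se = row[["Std. Error"]], t = row[["t value"]],
               df = row[["df"]], p = row[["Pr(>|t|)"]], n = nrow(d),
               formula = form)
  })
  do.call(rbind, out)
}

#' Proficiency effect on neural word-boundary decoding
#'
#' Mixed model `AUC ~ proficiency + (1|number of electrodes)` over
#' per-participant, per-fold decoding AUCs. The electrode-count grouping
#' is honoured literally (a random intercept per distinct electrode
#' count).
#'
#' @param df data.frame with columns `auc`, `proficiency`, `n_electrodes`
#'   (one row per participant x fold).
#' @return data.frame `estimate, se, t, df, p, n, formula`.
#' @export
proficiency_effect <- function(df) {
  stopifnot(all(c("auc", "proficiency", "n_electrodes") %in% names(df)))
  if (stats::var(df$proficiency) == 0)
    stop("proficiency is constant; the effect is not identifiable")
  form <- "auc ~ proficiency + (1|n_electrodes)"
  d <- df
  d$n_electrodes <- factor(d$n_electrodes)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(stats::as.formula(form), data = d,
                   control = lme4::lmerControl(check.conv.singular =
                                                 lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  co <- summary(fit)$coefficients["proficiency", ]
  data.frame(estimate = co[["Estimate"]], se = co[["Std. Error"]],
             t = co[["t value"]], df = co[["df"]], p = co[["Pr(>|t|)"]],
             n = nrow(d), formula = form)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates the end-to-end analysis: simulate the study, partition
#' unique variance per language, fit the condition mixed models, decode
#' word boundaries acoustically, compute AAI, decode boundaries neurally
#' in the native and foreign conditions on the same events, and contrast
#' the conditions across AAI bins. When `outdir` is given, each stage's
#' result is written as it completes (TSV/JSON plus a manifest with
#' content hashes); an existing stage file is reloaded instead of
#' recomputed, so deleting one intermediate resumes from that stage.
#'
#' @param config a [study_config()].
#' @param seed master seed.
#' @param outdir optional output directory.
#' @param n_events_decode events per class for the boundary decoders.
#' @param decode_folds decoder folds (default 20).
#' @return list: `study`, `partition`, `lme`, `acoustic`, `aai_records`,
#'   `neural_native`, `neural_foreign`, `bin_contrast`, `manifest`.
#' @export
run_study <- function(config = study_config(), seed = 1, outdir = NULL,
                      n_events_decode = 150, decode_folds = 20) {
  stage <- function(name, expr) {
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(outdir, paste0(name, ".rds"))
      if (file.exists(f)) return(readRDS(f))
      v <- force(expr)
      saveRDS(v, f)
      return(v)
    }
    force(expr)
  }
  study <- stage("study", simulate_study(config, seed))
  partition <- stage("partition", study_variance_partition(study, seed = seed))
  partition <- significance_gates(partition)
  lme <- stage("lme", lme_condition_effect(
    partition[partition$family %in%
                c("word_onset", "word_frequency", "word_length",
                  "phoneme_surprisal", "peakRate", "formant", "consonant"), ]))

  # boundary decoding on language A stimuli for all participants
  stimA <- study$stimuli$A
  events <- extract_events(stimA$sentences[stimA$train_ids])
  ne <- min(n_events_decode,
            min(table(events$label[!events$excluded])))
  ev <- sample_events(events, ne, ne, seed = seed + 5L)
  acoustic <- stage("acoustic", acoustic_decode(
    stimA$sentences, ev, folds = decode_folds, seed = seed + 6L))
  aai_records <- bin_aai(compute_aai(acoustic))

  meta <- study$electrode_meta
  native_e <- meta$electrode[meta$native_language == "A"]
  foreign_e <- meta$electrode[meta$native_language != "A"]
  stack_recording <- function(el) {
    rows <- lapply(study$participants$participant, function(p) {
      r <- study$recordings[[p]]$A
      keep <- meta$participant[match(el, meta$electrode)] == p
      if (!any(keep)) return(NULL)
      r$hfa[meta$within[match(el[keep], meta$electrode)], , drop = FALSE]
    })
    r1 <- study$recordings[[1]]$A
    structure(list(hfa = do.call(rbind, rows), fs = r1$fs,
                   alignment = r1$alignment), class = "neural_recording")
  }
  ev2 <- acoustic$events
  neural_native <- stage("neural_native", neural_decode(
    stack_recording(native_e), ev2, folds = decode_folds, seed = seed + 7L))
  neural_foreign <- stage("neural_foreign", neural_decode(
    stack_recording(foreign_e), ev2, folds = decode_folds, seed = seed + 7L))

  common <- intersect(neural_native$events$event_id, neural_foreign$events$event_id)
  rec2 <- aai_records[match(common, aai_records$event_id), ]
  bin_contrast <- bin_auc_contrast(
    neural_native$scores[match(common, neural_native$events$event_id)],
    neural_foreign$scores[match(common, neural_foreign$events$event_id)],
    rec2, seed = seed + 8L)

  manifest <- list(seed = seed, config = unclass(config),
                   n_events = nrow(ev2),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- list(study = study, partition = partition, lme = lme,
              acoustic = acoustic, aai_records = aai_records,
              neural_native = neural_native, neural_foreign = neural_foreign,
              bin_contrast = bin_contrast, manifest = manifest)
  if (!is.null(outdir)) {
    utils::write.table(partition, file.path(outdir, "variance_partition.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(lme, file.path(outdir, "lme_condition.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(aai_records, file.path(outdir, "aai_records.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(
      manifest = manifest,
      acoustic_auc = acoustic$fold_auc,
      neural_native_auc = neural_native$fold_auc,
      neural_foreign_auc = neural_foreign$fold_auc,
      bin_contrast = bin_contrast$per_bin,
      anova = bin_contrast$anova),
      file.path(outdir, "results.json"), auto_unbox = TRUE, digits = NA)
    files <- list.files(outdir, full.names = TRUE)
    hashes <- tools::md5sum(files[!grepl("manifest.json$", files)])
    jsonlite::write_json(as.list(hashes), file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  res
}
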