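test_that("the native/foreign contrast is exactly the word-feature block", {
  # with zero noise, native minus foreign responses equal the word-feature
  # convolution; acoustic responses are identical
  lang <- make_language(1)
  lex <- build_lexicon(lang)
  sents <- lapply(sample_sentences(lang, 3, seed = 2), render_acoustics, seed = 3)
  streams <- lapply(sents, build_feature_stream, lexicon = lex)
  names(streams) <- 1:3
  streams <- scale_streams(streams, feature_scale_stats(streams))
  truth <- make_ground_truth_trf(2, seed = 4, noise_sd = 0)
  trials <- data.frame(trial = 1:3, sentence = 1:3)
  rn <- simulate_neural(streams, trials, truth, "native", seed = 5)
  rf <- simulate_neural(streams, trials, truth, "foreign", seed = 5)
  # foreign policy zeroes exactly the word-level features
  g <- truth$policy$foreign
  expect_equal(unname(g[word_level_features()]), rep(0, 4))
  expect_equal(unname(g[acoustic_features()]), rep(1, 12))
  # difference equals the word-block convolution, zero where no word features
  wtruth <- truth
  wtruth$beta[rep(!(truth$features %in% word_level_features()),
                  each = truth$n_lags), ] <- 0
  rw <- simulate_neural(streams, trials, wtruth, "native", seed = 5)
  diff_ <- rn$hfa - rf$hfa
  base <- matrix(wtruth$intercept, 2, ncol(rw$hfa))
  expect_equal(diff_, rw$hfa - base, tolerance = 1e-10)
  expect_error(simulate_neural(streams, trials, truth, "martian", seed = 1),
               "condition")
})

test_that("simulated studies have the declared structure", {
  cfg <- study_config(n_participants = 2, electrodes_per_participant = 3,
                      n_train_sentences = 6, n_test_sentences = 2,
                      n_repeats = 2)
  st <- simulate_study(cfg, seed = 7)
  expect_s3_class(st, "speech_study")
  expect_equal(nrow(st$electrode_meta), 6)
  expect_setequal(names(st$encoding), c("A", "B"))
  # condition assignment is native for one language each
  mA <- st$encoding$A$electrode_meta
  expect_setequal(unique(mA$condition), c("native", "foreign"))
  expect_true(all(mA$condition[mA$native_language == "A"] == "native"))
  # deterministic in the master seed
  st2 <- simulate_study(cfg, seed = 7)
  expect_equal(st$recordings$P1$A$hfa, st2$recordings$P1$A$hfa)
  expect_error(study_config(bogus = 1), "unknown config")
})

test_that("the condition mixed model stores its formula and finds effects", {
  set.seed(8)
  # synthetic partition table: word family has a true condition effect
  n_p <- 4; n_e <- 6
  meta <- expand.grid(electrode = seq_len(n_p * n_e), condition = c("native", "foreign"))
  meta$participant <- paste0("P", (meta$electrode - 1) %/% n_e + 1)
  meta$hemisphere <- ifelse(meta$electrode %% 2 == 0, "left", "right")
  meta$speaker_language <- ifelse(meta$condition == "native", "A", "B")
  part <- rbind(
    transform(meta, family = "word_onset", delta_r2 =
                0.002 + 0.03 * (condition == "native") + rnorm(nrow(meta), 0, 0.01)),
    transform(meta, family = "peakRate", delta_r2 =
                0.05 + rnorm(nrow(meta), 0, 0.01)))
  res <- suppressWarnings(lme_condition_effect(part))
  expect_equal(res$formula[1], speechTRF:::lme_formula_string)
  wo <- res[res$family == "word_onset", ]
  pr <- res[res$family == "peakRate", ]
  expect_gt(wo$estimate, 0)
  expect_lt(wo$p, 0.05)
  expect_gt(pr$p, 0.05)
})

test_that("permuted condition labels null the mixed-model effect", {
  set.seed(9)
  n <- 120
  meta <- data.frame(electrode = rep(1:60, 2),
                     condition = rep(c("native", "foreign"), each = 60),
                     participant = rep(paste0("P", rep(1:4, each = 15)), 2),
                     hemisphere = sample(c("left", "right"), n, TRUE),
                     speaker_language = sample(c("A", "B"), n, TRUE),
                     family = "word_onset")
  meta$delta_r2 <- rnorm(n, 0.01, 0.01)     # no condition dependence
  ps <- replicate(10, {
    meta$condition <- sample(meta$condition)
    suppressWarnings(lme_condition_effect(meta))$p
  })
  expect_gt(mean(ps > 0.05), 0.6)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.45)
})

test_that("proficiency scaling of the word signal is recovered", {
  set.seed(10)
  prof <- c(0.2, 0.5, 0.8, 1.0, 0.3, 0.9)
  df <- do.call(rbind, lapply(seq_along(prof), function(i)
    data.frame(participant = i, proficiency = prof[i],
               n_electrodes = sample(c(40, 50, 60), 1),
               auc = 0.5 + 0.25 * prof[i] + rnorm(15, 0, 0.04))))
  res <- suppressWarnings(proficiency_effect(df))
  expect_gt(res$estimate, 0)
  expect_lt(res$p, 0.05)
  expect_equal(res$formula, "auc ~ proficiency + (1|n_electrodes)")
  # a null word signal shows no proficiency dependence
  df$auc <- 0.5 + rnorm(nrow(df), 0, 0.04)
  expect_gt(suppressWarnings(proficiency_effect(df))$p, 0.01)
  df$proficiency <- 1
  expect_error(proficiency_effect(df), "constant")
})

test_that("shuffled proficiency is centred on zero", {
  set.seed(11)
  prof <- seq(0.1, 1, length.out = 6)
  df <- do.call(rbind, lapply(seq_along(prof), function(i)
    data.frame(participant = i, proficiency = prof[i],
               n_electrodes = 40 + i,
               auc = 0.5 + 0.3 * prof[i] + rnorm(10, 0, 0.03))))
  est <- replicate(20, {
    d2 <- df
    map <- sample(prof)
    d2$proficiency <- map[d2$participant]
    suppressWarnings(proficiency_effect(d2))$estimate
  })
  expect_lt(abs(mean(est)), 0.1)
})
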