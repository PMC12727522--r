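test_that("the scheme table implements all nine printed formulas", {
  sc <- family_schemes()
  expect_equal(nrow(sc), 9)
  expect_setequal(sc$family, c("sentence_onset", "peakRate", "consonant",
                               "formant", "word_onset", "word_frequency",
                               "word_length", "phoneme_surprisal",
                               "word_combined"))
  for (i in seq_len(nrow(sc))) {
    full <- unlist(sc$full[i]); red <- unlist(sc$reduced[i])
    expect_true(all(red %in% full))
    expect_setequal(unlist(sc$family_features[i]), setdiff(full, red))
  }
  # acoustic families: full model vs full minus family
  pr <- sc[sc$family == "peakRate", ]
  expect_setequal(unlist(pr$full), feature_names())
  expect_setequal(unlist(pr$reduced), setdiff(feature_names(), "peakRate"))
  # word frequency adds on top of acoustic + word onset
  wf <- sc[sc$family == "word_frequency", ]
  expect_setequal(unlist(wf$reduced), c(acoustic_features(), "word_onset"))
  # combined word features: full vs acoustic
  cb <- sc[sc$family == "word_combined", ]
  expect_setequal(unlist(cb$reduced), acoustic_features())
  # invalid scheme rejected
  bad <- list(full = list(acoustic_features()),
              reduced = list(c(acoustic_features(), "word_onset")))
  sc2 <- make_encoding_scenario(n_electrodes = 1, seed = 41,
                                n_train = 6, n_test = 2)
  expect_error(unique_variance(sc2$ed, bad), "subset")
})

test_that("identical full and reduced sets give exactly zero delta R2", {
  sc <- make_encoding_scenario(n_electrodes = 2, noise_sd = 1, seed = 42,
                               n_train = 10, n_test = 3)
  same <- list(full = list(acoustic_features()),
               reduced = list(acoustic_features()))
  uv <- unique_variance(sc$ed, same, seed = 1,
                        fits = new.env(parent = emptyenv()))
  expect_equal(uv$delta_r2, c(0, 0))
})

test_that("families absent from the generative model have small delta R2", {
  # foreign condition: word-level weights are exactly zero
  sc <- make_encoding_scenario(n_electrodes = 3, noise_sd = 1, seed = 43,
                               n_train = 24, n_test = 6,
                               condition = "foreign")
  uv <- unique_variance(sc$ed,
                        family_schemes()[family_schemes()$family == "word_combined", ],
                        seed = 2)
  expect_true(all(abs(uv$delta_r2) < 0.02))
})

test_that("planted word-onset effects are recovered with significant p", {
  truth <- make_ground_truth_trf(3, seed = 44, noise_sd = 1,
                                 amp_sd = c(word_onset = 3),
                                 fixed_amp_features = "word_onset")
  sc <- make_encoding_scenario(n_electrodes = 3, seed = 44, n_train = 24,
                               n_test = 6, truth = truth)
  scheme <- family_schemes()[family_schemes()$family == "word_onset", ]
  uv <- unique_variance(sc$ed, scheme, seed = 3)
  expect_true(all(uv$delta_r2 > 0.01))
  expect_gt(median(uv$delta_r2), 0.03)
  ps <- permutation_significance(sc$ed, scheme, n_perms = 40, seed = 4, uv = uv)
  expect_true(all(ps$p <= 2 / 40))
  expect_true(all(ps$p >= 1 / 40))   # never zero
})

test_that("unshifted family blocks reproduce the design columns", {
  sc <- make_encoding_scenario(n_electrodes = 1, seed = 45, n_train = 4,
                               n_test = 2)
  ed <- sc$ed
  fam <- "word_onset"
  blocks <- speechTRF:::family_lag_blocks(
    ed$streams_train, fam, ed$n_lags, ed$pre, ed$post, offsets = NULL)
  cols <- speechTRF:::design_cols(ed$train$design, fam)
  expect_equal(blocks, ed$train$design$X[, cols], ignore_attr = TRUE)
  # a full-block rotation is the identity
  blk <- vapply(ed$streams_train, nrow, integer(1)) + ed$pre + ed$post
  blocks2 <- speechTRF:::family_lag_blocks(
    ed$streams_train, fam, ed$n_lags, ed$pre, ed$post, offsets = blk)
  expect_equal(blocks2, blocks)
})

test_that("significance gates apply the printed strict inequalities", {
  df <- data.frame(electrode = 1:4, family = "word_onset", type = "word",
                   delta_r2 = c(0.001, 0.0011, 0.02, 0.02),
                   r2_full = c(0.2, 0.2, 0.049, 0.2),
                   r2_reduced = 0.1)
  g <- significance_gates(df)
  expect_equal(g$pass_uv, c(FALSE, TRUE, FALSE, TRUE))  # 0.001 exactly fails
  expect_equal(g$pass_profile, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("permutation count validation", {
  sc <- make_encoding_scenario(n_electrodes = 1, seed = 46, n_train = 4,
                               n_test = 2)
  scheme <- family_schemes()[family_schemes()$family == "word_onset", ]
  expect_error(permutation_significance(sc$ed, scheme, n_perms = 0), "n_perms")
})
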