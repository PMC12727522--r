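test_that("HFA extraction recovers an amplitude-modulated envelope", {
  t100 <- seq(0.01, 10, by = 0.01)
  target <- 1 + 0.8 * sin(2 * pi * t100)
  raw <- simulate_raw_broadband(target, seed = 2)
  rec <- extract_hfa(raw$signal, fs = 400)
  truth <- raw$amplitude[seq(1, length(raw$amplitude), 4)]
  expect_gt(cor(rec$hfa[1, ], truth), 0.95)
  expect_s3_class(rec, "neural_recording")
  expect_equal(rec$fs, 100)
})

test_that("broadband fixture handles degenerate targets and aliasing", {
  const <- rep(2, 400)
  raw <- simulate_raw_broadband(const, seed = 1)
  rec <- extract_hfa(raw$signal, fs = 400)
  # constant target: flat envelope up to filter ripple (checked pre-z-score
  # through near-zero variance relative to an AM case)
  expect_lt(diff(range(raw$amplitude)), 1e-9)
  expect_error(simulate_raw_broadband(const, fs = 250), "aliasing")
  # zero-amplitude target gives (numerically) silent output
  z <- simulate_raw_broadband(rep(0.0, 400), seed = 1)
  expect_lt(max(abs(z$signal)), 0.06 * 2)
})

test_that("extraction is gain-invariant and z-scores per block", {
  set.seed(3)
  x <- rnorm(4000)
  a <- extract_hfa(x, fs = 400)$hfa
  b <- extract_hfa(5.5 * x, fs = 400)$hfa
  expect_equal(a, b, tolerance = 1e-10)
  expect_equal(sd(a), 1, tolerance = 1e-6)
  expect_equal(mean(a), 0, tolerance = 1e-9)
  blocks <- rep(1:2, each = 500)
  c2 <- extract_hfa(x, fs = 400, blocks = blocks)$hfa
  expect_equal(sd(c2[1, blocks == 2]), 1, tolerance = 1e-6)
})

test_that("out-of-band signal is strongly attenuated", {
  # the same slow envelope modulating a 30 Hz (out-of-band) versus a 110 Hz
  # (in-band) carrier: only the in-band carrier's envelope is recovered
  t400 <- seq_len(8000) / 400
  env <- 1 + 0.8 * sin(2 * pi * 0.7 * t400)
  set.seed(5)
  noise <- 0.05 * rnorm(8000)
  lowf <- env * sin(2 * pi * 30 * t400) + noise
  inband <- env * sin(2 * pi * 110 * t400) + noise
  env100 <- env[seq(1, 8000, 4)]
  r_low <- cor(extract_hfa(lowf, fs = 400)$hfa[1, ], env100)
  r_in <- cor(extract_hfa(inband, fs = 400)$hfa[1, ], env100)
  expect_gt(r_in, 0.95)
  expect_lt(abs(r_low), 0.5)
})

test_that("input validation catches short or non-finite signals", {
  expect_error(extract_hfa(rnorm(100), fs = 400), "shorter")
  expect_error(extract_hfa(c(rnorm(999), NA), fs = 400), "finite")
  expect_error(extract_hfa(rnorm(1000), fs = 300), "fs")
})

test_that("baseline normalization is location-invariant and guarded", {
  sc <- make_encoding_scenario(n_electrodes = 2, noise_sd = 1, seed = 21,
                               n_train = 4, n_test = 2)
  rec <- sc$recording
  bn1 <- baseline_normalize(rec)
  rec2 <- rec
  rec2$hfa <- rec2$hfa + 3.14
  bn2 <- baseline_normalize(rec2)
  expect_equal(bn1$hfa, bn2$hfa, tolerance = 1e-10)
  # baseline window itself becomes mean 0, sd 1
  a <- bn1$alignment[1, ]
  bl <- bn1$hfa[1, a$baseline_start:(a$onset - 1)]
  expect_equal(mean(bl), 0, tolerance = 1e-10)
  expect_equal(sd(bl), 1, tolerance = 1e-10)
  # constant signal: degenerate baseline raises a named error
  rec3 <- rec
  rec3$hfa[] <- 7
  expect_error(baseline_normalize(rec3), "degenerate")
})

test_that("responsive electrodes are detected and nulls are not", {
  # 60 sentences, electrode 1 carries a 1.2-sd speech response, electrode 2
  # is pure noise
  set.seed(31)
  n_sent <- 60
  frames_per <- 50 + 120  # 0.5 s baseline + 1.2 s speech
  hfa <- matrix(rnorm(2 * n_sent * frames_per), 2)
  align <- data.frame(trial = seq_len(n_sent))
  align$start <- (align$trial - 1) * frames_per + 1
  align$baseline_start <- align$start
  align$onset <- align$start + 50
  align$offset <- align$start + frames_per - 1
  align$end <- align$offset
  for (i in seq_len(n_sent))
    hfa[1, align$onset[i]:align$offset[i]] <-
      hfa[1, align$onset[i]:align$offset[i]] + 1.2
  rec <- structure(list(hfa = hfa, fs = 100, alignment = align),
                   class = "neural_recording")
  rr <- select_speech_responsive(rec)
  expect_true(rr$electrodes$responsive[1])
  expect_false(rr$electrodes$responsive[2])
  expect_equal(rr$n_tests, 100)  # Bonferroni pools both windows
})

test_that("nine contiguous significant frames are not enough", {
  # response present only in the first 0.09 s of speech
  set.seed(32)
  n_sent <- 200
  frames_per <- 50 + 120
  hfa <- matrix(rnorm(n_sent * frames_per), 1)
  align <- data.frame(trial = seq_len(n_sent))
  align$start <- (align$trial - 1) * frames_per + 1
  align$baseline_start <- align$start
  align$onset <- align$start + 50
  align$offset <- align$start + frames_per - 1
  align$end <- align$offset
  for (i in seq_len(n_sent))
    hfa[1, align$onset[i] + 0:8] <- hfa[1, align$onset[i] + 0:8] + 3
  rec <- structure(list(hfa = hfa, fs = 100, alignment = align),
                   class = "neural_recording")
  rr <- select_speech_responsive(rec)
  expect_false(rr$electrodes$responsive[1])
  expect_equal(rr$electrodes$longest_run_onset_s[1], 0.09, tolerance = 1e-9)
})
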