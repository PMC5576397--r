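test_that("mean absolute first differences match hand evaluation", {
  expect_equal(first_difference(rep(3, 4)), 0)
  expect_equal(first_difference(c(1, -1, 1, -1, 1)), 2)
  expect_equal(first_difference(c(0, 1, 3, 2)), 4 / 3)
  expect_error(first_difference(1), class = "emdeeg_error_invalid_input")

  expect_equal(phase_first_difference(c(0, pi / 8, pi / 4, 3 * pi / 8)), pi / 8)
  expect_equal(phase_first_difference(rep(1.3, 10)), 0)

  az <- analytic_signal(tone(8, cosine = TRUE))
  dp <- phase_first_difference(az$phase[interior])
  expect_lt(abs(dp - pi / 8) / (pi / 8), 0.05)
})

test_that("normalized energy and its log behave on the trivial cases", {
  x <- tone(8)
  expect_equal(normalized_energy(x, x), 1)
  expect_equal(normalized_energy(x / 2, x), 0.25)
  expect_equal(normalized_energy(numeric(640), x), 0)
  expect_error(normalized_energy(x, numeric(640)),
               class = "emdeeg_error_degenerate_signal")

  expect_equal(log_normalized_energy(1), 0)
  expect_equal(log_normalized_energy(exp(2)), 2)
  expect_equal(log_normalized_energy(0.25), log(0.25))
  expect_warning(v <- log_normalized_energy(0), "clamped")
  expect_equal(v, log(1e-12))
})

test_that("extract_features produces the deterministic (channel, level, feature) grid", {
  seg8 <- matrix(rep(tone(8), 8), nrow = 8, byrow = TRUE,
                 dimnames = list(paste0("c", 1:8), NULL))
  fv <- extract_features(seg8, imf_levels = 1)
  expect_equal(nrow(fv), 24)  # 8 channels x 1 level x 3 features
  expect_equal(levels(fv$feature), c("Dt", "Dp", "logEnorm"))
  expect_equal(as.character(fv$feature[1:3]), c("Dt", "Dp", "logEnorm"))
  expect_equal(fv$channel[1:3], rep("c1", 3))

  # identical channels give identical triples
  vals <- matrix(fv$value, nrow = 3)
  expect_lt(max(abs(vals - vals[, 1])), 1e-9)

  expect_error(extract_features(seg8, channels = "nope"),
               class = "emdeeg_error_missing_channel")
})

test_that("requesting all 5 levels on 32 channels yields a 480-long feature vector", {
  set.seed(21)
  seg <- matrix(rnorm(32 * 640), nrow = 32,
                dimnames = list(deap_channels(), NULL))
  fv <- extract_features(seg, imf_levels = 1:5)
  expect_equal(nrow(fv), 480)  # 32 x 5 x 3
  expect_true(all(is.finite(fv$value)))
  # missing levels (if any decomposition stopped early) carry the sentinel
  sentinel <- fv$value[fv$feature == "logEnorm" & fv$value < log(1e-11)]
  expect_true(all(abs(sentinel - log(1e-12)) < 1e-9))
})

test_that("Dp and Enorm are amplitude-invariant while Dt scales linearly", {
  set.seed(5)
  seg <- matrix(rnorm(2 * 640), nrow = 2, dimnames = list(c("a", "b"), NULL))
  f1 <- extract_features(seg, imf_levels = 1)
  f2 <- extract_features(seg * 7, imf_levels = 1)
  pick <- function(fv, feat) fv$value[fv$feature == feat]
  expect_lt(max(abs(pick(f2, "Dp") - pick(f1, "Dp"))), 1e-6)
  expect_lt(max(abs(pick(f2, "logEnorm") - pick(f1, "logEnorm"))), 1e-9)
  expect_lt(max(abs(pick(f2, "Dt") / pick(f1, "Dt") - 7)), 1e-6)
})

test_that("Dp decreases with IMF level on broadband noise", {
  wins <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    seg <- matrix(rnorm(640), nrow = 1, dimnames = list("z", NULL))
    fv <- extract_features(seg, imf_levels = 1:2)
    dp <- fv$value[fv$feature == "Dp"]
    dp[1] > dp[2]
  })
  expect_gte(mean(wins), 0.95)
})

test_that("feature_table rows are keyed by subject/trial/segment with labels", {
  ds <- make_two_class_dataset(small_spec(n_trials = 4, trial_sec = 10))[[1]]
  ft <- feature_table(ds, channels = c("ch02", "ch03"), imf_levels = 1)
  expect_equal(nrow(ft), 4 * 2)  # 4 trials x 2 segments
  expect_named(ft, c("subject_id", "trial", "segment", "valence_rating",
                     "arousal_rating", "valence_label", "arousal_label",
                     "ch02_imf1_Dt", "ch02_imf1_Dp", "ch02_imf1_logEnorm",
                     "ch03_imf1_Dt", "ch03_imf1_Dp", "ch03_imf1_logEnorm"))
  # deterministic: identical input gives an identical table
  ft2 <- feature_table(ds, channels = c("ch02", "ch03"), imf_levels = 1)
  expect_identical(ft, ft2)
})
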