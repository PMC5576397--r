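test_that("F1 matches hand-computed confusion matrices", {
  perfect <- matrix(c(10, 0, 0, 10), 2, 2,
                    dimnames = list(predicted = c("high", "low"),
                                    truth = c("high", "low")))
  expect_equal(f1_score(perfect), 1)

  cm_v <- matrix(c(6664, 2024, 2723, 3949), 2, 2,
                 dimnames = list(predicted = c("high", "low"),
                                 truth = c("high", "low")))
  expect_equal(f1_score(cm_v), 13328 / 18075)
  expect_equal(round(f1_score(cm_v), 4), 0.7374)

  cm_a <- matrix(c(7493, 1555, 2748, 3564), 2, 2,
                 dimnames = list(predicted = c("high", "low"),
                                 truth = c("high", "low")))
  expect_equal(round(f1_score(cm_a), 4), 0.7769)

  all_low <- matrix(c(0, 5, 0, 5), 2, 2)
  expect_equal(f1_score(all_low), 0)
})

test_that("leave-one-trial-out separates a well-separated synthetic subject", {
  rep <- eval_synthetic(small_spec(separation = 3, seed = 7))
  expect_gte(rep$accuracy, 90)
  # bookkeeping: one fold per trial, confusion total = all test samples
  expect_equal(nrow(rep$per_fold), 16)
  expect_equal(sum(rep$confusion), sum(rep$per_fold$n_test))
  expect_equal(rep$accuracy,
               100 * sum(rep$per_fold$n_correct) / sum(rep$per_fold$n_test),
               tolerance = 1e-12)
  g <- glance(rep)
  expect_equal(g$accuracy, rep$accuracy)
  expect_equal(g$tp + g$fp + g$fn + g$tn, sum(rep$confusion))
})

test_that("shuffled labels drop accuracy to chance", {
  ds <- make_two_class_dataset(small_spec(separation = 3, seed = 8,
                                          n_trials = 40, trial_sec = 30))[[1]]
  ft <- feature_table(ds, channels = c("ch02", "ch03"), imf_levels = 1)
  trials <- unique(ft$trial)
  trial_labs <- ft$valence_label[match(trials, ft$trial)]
  accs <- sapply(1:10, function(s) {
    set.seed(s)
    # permute labels at the trial level so segments stay consistent
    perm_labs <- trial_labs[sample(length(trials))]
    shuf <- ft
    shuf$valence_label <- perm_labs[match(ft$trial, trials)]
    if (length(unique(shuf$valence_label)) < 2) return(NA)
    loto_evaluate(shuf, "valence")$accuracy
  })
  expect_gt(mean(accs, na.rm = TRUE), 40)
  expect_lt(mean(accs, na.rm = TRUE), 60)
})

test_that("held-out trial data cannot influence other folds", {
  ds <- make_two_class_dataset(small_spec(n_trials = 8, trial_sec = 10,
                                          seed = 3))[[1]]
  ft <- feature_table(ds, channels = c("ch02", "ch03"), imf_levels = 1)
  base <- loto_evaluate(ft, "valence", keep_fold_fits = TRUE)
  # wreck the features of trial 5: fold 5 trains on the other trials only,
  # so its scaler statistics and fitted decision function must not move
  mangled <- ft
  feat_cols <- grep("_imf1_", names(ft), value = TRUE)
  mangled[mangled$trial == 5, feat_cols] <- 1e6
  pert <- loto_evaluate(mangled, "valence", keep_fold_fits = TRUE)
  expect_identical(base$fold_fits[["5"]], pert$fold_fits[["5"]])
  # contrast: folds that legitimately train on trial 5 do see the change
  expect_false(identical(base$fold_fits[["1"]], pert$fold_fits[["1"]]))
})

test_that("single-trial or single-class inputs are invalid", {
  ds <- make_two_class_dataset(small_spec(n_trials = 4, trial_sec = 10))[[1]]
  ft <- feature_table(ds, channels = "ch02", imf_levels = 1)
  expect_error(loto_evaluate(dplyr::filter(ft, trial == 1), "valence"),
               class = "emdeeg_error_invalid_input")
  one_class <- ft
  one_class$valence_label <- factor("high", levels = c("low", "high"))
  expect_error(loto_evaluate(one_class, "valence"),
               class = "emdeeg_error_invalid_input")
})

test_that("paired t-test verdicts follow the p-value and degenerate rules", {
  a <- c(60, 65, 70, 72, 68)
  expect_equal(paired_ttest(a, a)$p_value, 1)
  expect_true(paired_ttest(a, a)$similar)

  set.seed(31)
  b <- rnorm(32, mean = 60, sd = 5)
  shifted <- b + 10 + rnorm(32, sd = 1)
  res <- paired_ttest(shifted, b)
  expect_lt(res$p_value, 0.05)
  expect_false(res$similar)

  # cross-check against a direct t-distribution evaluation on 5 pairs
  x <- c(61, 63, 59, 70, 66); y <- c(60, 61, 62, 65, 64)
  d <- x - y
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- 2 * stats::pt(-abs(t_stat), df = 4)
  res2 <- paired_ttest(x, y)
  expect_equal(res2$statistic, t_stat, tolerance = 1e-6)
  expect_equal(res2$p_value, p_ref, tolerance = 1e-6)

  expect_error(paired_ttest(a, a + 2), class = "emdeeg_error_degenerate_signal")
  expect_error(paired_ttest(1:2, 3:4), class = "emdeeg_error_invalid_input")
})

test_that("evaluate_subjects aggregates across subjects and flags exclusions", {
  spec <- synthetic_spec(n_subjects = 2, n_trials = 8, trial_sec = 10,
                         n_channels = 2, informative_channels = 1:2,
                         separation = 3, seed = 12)
  sets <- make_two_class_dataset(spec)
  ft <- feature_table(sets, imf_levels = 1)
  res <- evaluate_subjects(ft, "valence")
  expect_equal(nrow(res), 2)
  expect_true(all(res$included))
  expect_equal(attr(res, "mean_accuracy"), mean(res$accuracy))
  expect_equal(sum(attr(res, "pooled_confusion")),
               sum(res$tp + res$fp + res$fn + res$tn))
})
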