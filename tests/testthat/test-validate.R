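# Labeling rules and the balanced Monte-Carlo leave-one-out engine:
# coverage, balance, leakage, determinism, chance behavior.

test_that("MMSE labeling follows the increase / constant / decrease rule", {
  tab <- data.frame(subject_id = c("A", "B", "C"),
                    mmse_pre = c(18, 20, 22), mmse_post = c(21, 20, 19))
  lab <- label_subjects(tab)
  expect_equal(lab$label, c("TMS+", "TMS+", "TMS-"))
  expect_equal(as.integer(attr(lab, "class_counts")[c("TMS+", "TMS-")]), c(2, 1))
  tab$mmse_post[2] <- NA
  expect_error(label_subjects(tab), "subject B")
  tab$mmse_post[2] <- 35
  expect_error(label_subjects(tab), "\\[0, 30\\]")
})

test_that("maximal balanced subsets have size twice the minority count", {
  set.seed(1)
  s1 <- max_balanced_subset(sprintf("p%d", 1:7), sprintf("n%d", 1:6))
  expect_length(s1, 12)
  s2 <- max_balanced_subset(sprintf("p%d", 1:8), sprintf("n%d", 1:5))
  expect_length(s2, 10)
  expect_equal(sum(grepl("^p", s2)), 5)
  s3 <- max_balanced_subset(sprintf("p%d", 1:3), sprintf("n%d", 1:3))
  expect_setequal(s3, c(sprintf("p%d", 1:3), sprintf("n%d", 1:3)))
  expect_error(max_balanced_subset(character(0), "n1"), "non-empty")
})

test_that("the trial-count formula counts subsets times partitions, capped", {
  # nothing to drop when balanced; C(7,1) ways for a 7/6 split
  expect_equal(n_trials_required(6, 6, cap = Inf, val_per_class = 0), 1L)
  expect_equal(n_trials_required(7, 6, cap = Inf, val_per_class = 0), 7L)
  # balanced 6/6 with 1 validation subject per class: 6*6 partitions
  expect_equal(n_trials_required(6, 6, cap = Inf, val_per_class = 1), 36L)
  # the default cap of 50 governs the realistic cohort sizes
  expect_equal(n_trials_required(7, 6), 50L)
  expect_equal(n_trials_required(8, 5), 50L)
})

test_that("leave-one-out covers every subject exactly once", {
  fs <- toy_feature_set(effect = 3, seed = 2)
  rep <- mc_leave_one_out(fs, n_trials = 5, seed = 3)
  expect_equal(nrow(rep$per_subject), 14)
  expect_true(all(rep$per_subject$n_trials == 5))
  expect_equal(rep$n_trials_total, 70)
  # overall mean equals the mean of per-trial accuracies (equal trials per
  # subject, so also the mean of per-subject accuracies)
  expect_equal(rep$overall, mean(rep$per_subject$accuracy))
  expect_true(all(rep$per_subject$accuracy >= 0 & rep$per_subject$accuracy <= 100))
})

test_that("a strongly separable cohort reaches 100% and a pure-noise cohort does not", {
  fs <- toy_feature_set(effect = 6, seed = 4)
  rep <- mc_leave_one_out(fs, n_trials = 5, seed = 5)
  expect_equal(rep$overall, 100)
  # direct classification on the same cohort
  dc <- direct_classification(fs, n_random_trials = 10, seed = 6)
  expect_equal(dc$overall, 100)
  expect_equal(dc$sd_trials, 0)
})

test_that("under the null the engine behaves at chance (permutation band)", {
  # no class signal at all: accuracy must fall inside the exact null band
  # for 14 subjects (binomial 2.5%..97.5% of the per-subject coin flip)
  accs <- vapply(1:3, function(s) {
    fs <- toy_feature_set(effect = 0, seed = 10 + s)
    mc_leave_one_out(fs, n_trials = 10, seed = s)$overall
  }, numeric(1))
  lo <- 100 * qbinom(0.025, 14, 0.5) / 14
  hi <- 100 * qbinom(0.975, 14, 0.5) / 14
  expect_true(mean(accs) >= lo && mean(accs) <= hi)
  # binomial test on the fold successes of one run
  fs <- toy_feature_set(effect = 0, seed = 21)
  rep <- mc_leave_one_out(fs, n_trials = 10, seed = 2)
  folds_correct <- sum(rep$per_subject$accuracy > 50)
  expect_gt(stats::binom.test(folds_correct, 14, 0.5)$p.value, 0.01)
})

test_that("identical seeds reproduce identical reports", {
  fs <- toy_feature_set(effect = 1, seed = 7)
  r1 <- mc_leave_one_out(fs, n_trials = 4, seed = 42, audit = TRUE)
  r2 <- mc_leave_one_out(fs, n_trials = 4, seed = 42, audit = TRUE)
  expect_identical(r1, r2)
  r3 <- direct_classification(fs, n_random_trials = 8, seed = 42)
  r4 <- direct_classification(fs, n_random_trials = 8, seed = 42)
  expect_identical(r3, r4)
})

test_that("no trial leaks the test subject and every split is balanced", {
  fs <- toy_feature_set(effect = 1, seed = 8)
  rep <- mc_leave_one_out(fs, n_trials = 6, seed = 9, audit = TRUE)
  lab <- setNames(fs$subjects$label, fs$subjects$subject_id)
  for (tr in rep$audit) {
    expect_false(tr$test_id %in% c(tr$train_ids, tr$val_ids))
    expect_length(intersect(tr$train_ids, tr$val_ids), 0)
    expect_equal(sum(lab[tr$train_ids] == "TMS+"),
                 sum(lab[tr$train_ids] == "TMS-"))
    expect_equal(sum(lab[tr$val_ids] == "TMS+"),
                 sum(lab[tr$val_ids] == "TMS-"))
  }
  # every subject appears as test
  expect_setequal(unique(vapply(rep$audit, `[[`, character(1), "test_id")),
                  fs$subjects$subject_id)
})

test_that("infeasible folds are skipped with a reason, or the run errors when all are", {
  fs <- toy_feature_set(n_pos = 2, n_neg = 2, seed = 11)
  expect_error(mc_leave_one_out(fs, n_trials = 2, seed = 1), "infeasible")
  # with no validation subjects the same cohort is feasible
  rep <- mc_leave_one_out(fs, n_trials = 2, seed = 1, val_per_class = 0)
  expect_equal(nrow(rep$per_subject), 4)
  expect_length(rep$skipped_folds, 0)
})

test_that("direct classification uses the requested stratified train size", {
  fs <- toy_feature_set(effect = 2, seed = 12)
  rep <- direct_classification(fs, train_fraction = 9 / 14,
                               n_random_trials = 5, seed = 13, audit = TRUE)
  for (tr in rep$audit) {
    expect_length(tr$train_ids, 9)       # 5 TMS+ + 4 TMS- of 8/6
    expect_length(intersect(tr$train_ids, tr$test_ids), 0)
  }
  expect_error(direct_classification(fs, train_fraction = 0.99),
               "class empty")
})

test_that("size sweeps cover the feasible grid and stay perfect when separable", {
  fs <- toy_feature_set(effect = 6, seed = 14)
  sw <- size_sweep(fs, mode = "train", sizes = c(1, 2, 3), n_trials = 3,
                   selector = "band_restrict",
                   selector_params = list(band = "theta"))
  expect_equal(nrow(sw), 3)
  expect_equal(sw$total_size, c(2, 4, 6))
  expect_true(all(sw$mean_accuracy == 100))
  sv <- size_sweep(fs, mode = "val", sizes = c(1, 2), train_per_class = 2,
                   n_trials = 3)
  expect_equal(nrow(sv), 2)
})
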