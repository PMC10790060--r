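make_manifest <- function(ns, si, sa) {
  groups <- rep(c("NS", "SI", "SA"), times = c(ns, si, sa))
  data.frame(subject_id = sprintf("s%03d", seq_along(groups)), group = groups,
             binary_target = as.integer(groups != "NS"),
             stringsAsFactors = FALSE)
}

test_that("sixfold stratified split of the 83-subject cohort gives 14x5 + 13", {
  manifest <- make_manifest(35, 26, 22)
  folds <- make_folds(manifest, k = 6, seed = 1)
  expect_identical(sort(fold_sizes(folds), decreasing = TRUE),
                   c(14L, 14L, 14L, 14L, 14L, 13L))
  # every subject in exactly one fold
  expect_identical(length(folds$fold), 83L)
  expect_true(all(folds$fold %in% 1:6))
  # every stratum represented in every fold
  for (g in c("NS", "SI", "SA")) {
    in_fold <- table(folds$fold[manifest$subject_id[manifest$group == g]])
    expect_identical(length(in_fold), 6L)
  }
  expect_identical(make_folds(manifest, k = 6, seed = 1)$fold, folds$fold)
  expect_false(identical(make_folds(manifest, k = 6, seed = 2)$fold, folds$fold))
})

test_that("fold sizes stay within one of each other across configurations", {
  for (seed in 1:5) {
    manifest <- make_manifest(2, 2, 2)
    f6 <- make_folds(manifest, k = 6, seed = seed)
    expect_true(all(fold_sizes(f6) == 1L))
    manifest2 <- make_manifest(20, 14, 14)
    f3 <- make_folds(manifest2, k = 3, seed = seed)
    expect_lte(diff(range(fold_sizes(f3))), 1L)
  }
  expect_error(make_folds(make_manifest(2, 1, 1), k = 6), "folds than subjects")
})

test_that("fold roles rotate: each fold tests once, validation is the next fold", {
  k <- 6L
  test_folds <- integer(0)
  for (f in 1:k) {
    roles <- csefc:::.fold_roles(f, k)
    test_folds <- c(test_folds, roles$test)
    expect_identical(roles$val, if (f == k) 1L else f + 1L)
    expect_identical(sort(c(roles$test, roles$val, roles$train)), 1:k)
  }
  expect_identical(sort(test_folds), 1:k)
})

test_that("accuracy_ci is the clamped t interval", {
  flat <- accuracy_ci(rep(0.8, 6))
  expect_equal(unname(flat), c(0.8, 0.8, 0.8))
  two <- accuracy_ci(c(1.0, 0.5))
  expect_equal(two[["mean"]], 0.75)
  expect_equal(two[["ci_high"]], 1)  # clamped
  # CI width shrinks as k grows at fixed sd
  acc4 <- c(0.7, 0.8, 0.7, 0.8)
  acc8 <- rep(acc4, 2)
  w4 <- diff(accuracy_ci(acc4)[c("ci_low", "ci_high")])
  w8 <- diff(accuracy_ci(acc8)[c("ci_low", "ci_high")])
  expect_lt(w8, w4)
  expect_error(accuracy_ci(0.8), "at least 2")
})

test_that("rank_rois applies strict thresholding and per-fold reliability", {
  report <- data.frame(
    roi_label = c(1L, 2L, 3L),
    fold1_accuracy = c(0.8, 0.6, 0.8),
    fold2_accuracy = c(0.8, 0.6, 0.8),
    fold3_accuracy = c(0.7, 0.6, 0.8),
    mean_accuracy = c(mean(c(0.8, 0.8, 0.7)), 0.6, 0.8))
  ranked <- rank_rois(report, threshold = 0.75)
  # roi 1 mean 0.767 > 0.75 -> above, but fold3 fails reliability
  expect_identical(ranked$above_threshold, c(3L, 1L))
  expect_identical(ranked$reliable, 3L)
  none <- rank_rois(report, threshold = 0.9)
  expect_length(none$above_threshold, 0L)
})

test_that("ensemble vote is majority with ties toward suicidality", {
  expect_identical(ensemble_predict(c(1, 1, 0)), 1L)
  expect_identical(ensemble_predict(c(0, 0, 0, 1)), 0L)
  expect_identical(ensemble_predict(c(0, 1)), 1L)
  votes <- matrix(c(1, 1, 0, 0, 0, 1), 2, 3,
                  dimnames = list(c("a", "b"), NULL))
  # row a = (1,0,0) -> majority 0; row b = (1,0,1) -> majority 1
  expect_identical(ensemble_labels(votes), c(a = 0L, b = 1L))
})

test_that("summary t statistic reproduces the education group comparison", {
  t_edu <- summary_t_test(7.9, 2.9, 35, 9.2, 3.6, 48)
  expect_equal(round(t_edu, 1), -1.8)
  expect_identical(summary_t_test(5, 1, 10, 5, 1, 10), 0)
  # sign anti-symmetry
  expect_equal(summary_t_test(9.2, 3.6, 48, 7.9, 2.9, 35), -t_edu)
  expect_identical(summary_t_test(1, 0, 5, 2, 0, 5), -Inf)
  # agreement with t.test on reconstructed data: two-point summary
  x <- c(4, 6); y <- c(1, 3, 5)
  expect_equal(summary_t_test(mean(x), sd(x), 2, mean(y), sd(y), 3),
               unname(t.test(x, y, var.equal = TRUE)$statistic))
})

test_that("seed-ROI cross-validation partitions subjects and guards leakage", {
  fx <- small_cohort_fixture()
  atlas <- make_toy_atlas(c(14, 14, 14), 4, seed = 8)
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  folds <- make_folds(fx$manifest, k = 3, seed = 3)
  hyper <- train_hyper(max_epochs = 3, batch_size = 8,
                       early_stop_patience = 2, seed = 5)
  res <- run_seed_roi_cv(fx$matrices, fx$manifest, folds, 1, atlas, spec, hyper)
  expect_length(res$accuracies, 3L)
  expect_true(all(res$accuracies >= 0 & res$accuracies <= 1))
  # every subject tested exactly once
  expect_identical(sort(res$predictions$subject_id), sort(fx$manifest$subject_id))
  # fold-scoped normalization: no test-fold NS subject in the reference set
  for (f in 1:3) {
    test_ids <- fx$manifest$subject_id[folds$fold[fx$manifest$subject_id] == f]
    expect_length(intersect(res$reference_ids[[f]], test_ids), 0L)
  }
  expect_error(run_seed_roi_cv(fx$matrices[-1], fx$manifest, folds, 1, atlas,
                               spec, hyper),
               "missing")
})

test_that("run_full_cv reports one row per seed ROI with consistent flags", {
  fx <- small_cohort_fixture()
  atlas <- make_toy_atlas(c(14, 14, 14), 4, seed = 8)
  spec <- cnn_spec(c(14, 14, 14), profile = "reduced")
  folds <- make_folds(fx$manifest, k = 3, seed = 3)
  hyper <- train_hyper(max_epochs = 3, batch_size = 8,
                       early_stop_patience = 2, seed = 5)
  out <- run_full_cv(fx$matrices, fx$manifest, folds, atlas, spec, hyper,
                     seed_rois = c(1, 3))
  expect_identical(nrow(out$report), 2L)
  expect_identical(out$report$roi_label, c(1L, 3L))
  with(out$report, {
    expect_true(all(ci_low <= mean_accuracy + 1e-12))
    expect_true(all(mean_accuracy <= ci_high + 1e-12))
    expect_identical(above_threshold, mean_accuracy > 0.75)
  })
  # vote matrix covers every subject and ROI
  expect_identical(dim(out$votes), c(12L, 2L))
  expect_false(anyNA(out$votes))
})
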