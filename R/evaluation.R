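#' Stratified fold assignment
#'
#' Randomly partitions subjects into `k` near-equal folds while keeping every
#' clinical stratum (NS, SI, SA) represented in every fold whenever the
#' stratum has at least `k` members. Each stratum is shuffled and dealt a
#' base allocation of `floor(n_stratum / k)` subjects per fold; stratum
#' remainders are then placed greedily on the folds with the smallest
#' current totals (ties to the lowest fold index), which keeps overall fold
#' sizes within one of each other — for the 35/26/22 cohort and k = 6 this
#' yields the sizes 14, 14, 14, 14, 14, 13.
#'
#' @param manifest Data frame with columns `subject_id` and `group`.
#' @param k Number of folds (default 6).
#' @param seed RNG seed for the per-stratum shuffles.
#' @return Object of class `fold_assignment`: `k`, `seed`, and `fold`, a
#'   named integer vector mapping subject_id to fold index 1..k.
#' @export
make_folds <- function(manifest, k = 6L, seed = 1L) {
  k <- as.integer(k)
  n <- nrow(manifest)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("more folds than subjects")
  if (anyDuplicated(manifest$subject_id)) stop("subject ids must be unique")
  old <- .restore_seed(seed)
  on.exit(old())
  fold <- integer(n)
  names(fold) <- manifest$subject_id
  totals <- integer(k)
  strata <- unique(manifest$group)
  for (g in strata) {
    ids <- manifest$subject_id[manifest$group == g]
    ids <- ids[sample(length(ids))]
    base <- length(ids) %/% k
    counts <- rep(base, k)
    for (extra in seq_len(length(ids) %% k)) {
      target <- which.min(totals + counts)  # ties -> lowest index
      counts[target] <- counts[target] + 1L
    }
    assign_to <- rep(seq_len(k), times = counts)
    fold[ids] <- assign_to
    totals <- totals + counts
  }
  structure(list(k = k, seed = as.integer(seed), fold = fold),
            class = "fold_assignment")
}

#' Fold sizes of an assignment
#' @param folds A `fold_assignment`.
#' @return Integer vector of length k.
#' @export
fold_sizes <- function(folds) {
  tabulate(folds$fold, nbins = folds$k)
}

#' Mean and t-based 95% confidence interval of per-fold accuracies
#'
#' `mean +/- t_{level, k-1} * sd / sqrt(k)`, clamped to `[0, 1]`.
#'
#' @param accuracies Numeric vector of per-fold accuracies (k >= 2).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(mean, ci_low, ci_high)`.
#' @export
accuracy_ci <- function(accuracies, level = 0.95) {
  k <- length(accuracies)
  if (k < 2L) stop("need at least 2 folds for a confidence interval")
  m <- mean(accuracies)
  half <- stats::qt(1 - (1 - level) / 2, df = k - 1L) * stats::sd(accuracies) / sqrt(k)
  c(mean = m, ci_low = max(0, m - half), ci_high = min(1, m + half))
}

#' Rank seed ROIs by cross-validated accuracy
#'
#' @param report An `roi_accuracy_report` data frame (see [run_full_cv()]).
#' @param threshold Accuracy threshold; comparisons are strict (`>`).
#' @return List with `above_threshold` (ROI labels with mean accuracy above
#'   the threshold, sorted by descending mean) and `reliable` (ROI labels
#'   above the threshold in every fold).
#' @export
rank_rois <- function(report, threshold = 0.75) {
  if (!nrow(report)) stop("empty report")
  ord <- order(-report$mean_accuracy)
  above <- report$roi_label[ord][report$mean_accuracy[ord] > threshold]
  fold_cols <- grep("^fold[0-9]+_accuracy$", names(report), value = TRUE)
  reliable <- report$roi_label[
    apply(report[fold_cols] > threshold, 1L, all)]
  list(above_threshold = above, reliable = reliable)
}

#' Majority-vote ensemble over seed-ROI classifiers
#'
#' Aggregates the per-seed-ROI predicted labels for one subject; ties break
#' toward the suicidality class (1).
#'
#' @param votes Integer vector of 0/1 votes (>= 1).
#' @return 0 or 1.
#' @export
ensemble_predict <- function(votes) {
  votes <- as.integer(votes)
  if (!length(votes)) stop("need at least one vote")
  if (sum(votes == 1L) >= sum(votes == 0L)) 1L else 0L
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Classical pooled-variance two-sample t computed from group means, SDs and
#' sizes, as used for demographic group comparisons reported as
#' `mean +/- sd`. With zero pooled variance the statistic is 0 for equal
#' means and signed infinity otherwise.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return The t statistic (positive when group 1 has the larger mean).
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  pooled_var <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  diff <- mean1 - mean2
  if (pooled_var == 0) return(if (diff == 0) 0 else sign(diff) * Inf)
  diff / sqrt(pooled_var * (1 / n1 + 1 / n2))
}

# Fold roles for CV iteration f: test = f, validation = next fold, train = rest.
.fold_roles <- function(f, k) {
  val <- (f %% k) + 1L
  list(test = f, val = val, train = setdiff(seq_len(k), c(f, val)))
}

# Normalized seed-ROI volumes for a set of subjects given reference stats.
.painted_volumes <- function(matrices, ids, stats, seed_roi, atlas) {
  lapply(ids, function(id) {
    nm <- normalize_cse_matrix(matrices[[id]], stats)
    paint_cse_volume(nm, seed_roi, atlas)
  })
}

#' Cross-validate the classifier for one seed ROI
#'
#' For each fold f: the f-th fold is the test set, the next fold (cyclic) is
#' the validation set used for early stopping, and the remaining k - 2 folds
#' train the network. Reference statistics for CSE normalization are fitted,
#' per fold, on the non-suicidal subjects of the training folds only
#' (`normalization = "fold"`, the leakage-safe default) or once on all
#' non-suicidal subjects (`"global"`).
#'
#' @param matrices Named list of raw `cse_matrix` objects (all subjects).
#' @param manifest Cohort manifest (`subject_id`, `group`, `binary_target`).
#' @param folds A [make_folds()] assignment.
#' @param seed_roi Seed ROI index.
#' @param atlas `atlas_volume` used to paint the input volumes.
#' @param spec A [cnn_spec()] matching the atlas extents.
#' @param hyper A [train_hyper()]; each fold trains from scratch with a
#'   fold-specific seed derived from `hyper$seed`.
#' @param normalization `"fold"` or `"global"`.
#' @return List with `accuracies` (length k), `predictions` (per-subject
#'   data frame: subject_id, fold, truth, predicted), and `reference_ids`
#'   (per fold, subjects used for normalization).
#' @export
run_seed_roi_cv <- function(matrices, manifest, folds, seed_roi, atlas, spec,
                            hyper = train_hyper(),
                            normalization = c("fold", "global")) {
  normalization <- match.arg(normalization)
  k <- folds$k
  if (k < 3L)
    stop("cross-validation needs k >= 3 folds (test, validation, training)")
  ids <- manifest$subject_id
  missing <- setdiff(ids, names(matrices))
  if (length(missing))
    stop("CSE matrices missing for subjects: ", paste(missing, collapse = ", "))
  labels <- stats::setNames(manifest$binary_target, ids)
  ns_ids <- ids[manifest$group == "NS"]
  global_stats <- if (normalization == "global")
    fit_reference_stats(matrices, ns_ids) else NULL
  accuracies <- numeric(k)
  predictions <- list()
  reference_ids <- vector("list", k)
  for (f in seq_len(k)) {
    roles <- .fold_roles(f, k)
    train_ids <- ids[folds$fold[ids] %in% roles$train]
    val_ids <- ids[folds$fold[ids] == roles$val]
    test_ids <- ids[folds$fold[ids] == roles$test]
    ref <- if (normalization == "fold") {
      stats_f <- fit_reference_stats(matrices, intersect(train_ids, ns_ids))
      stats_f
    } else global_stats
    reference_ids[[f]] <- ref$reference_ids
    fold_hyper <- hyper
    fold_hyper$seed <- as.integer((hyper$seed + 1000003 * f) %% 2147483647)
    model <- train_cnn(spec,
                       .painted_volumes(matrices, train_ids, ref, seed_roi, atlas),
                       labels[train_ids],
                       .painted_volumes(matrices, val_ids, ref, seed_roi, atlas),
                       labels[val_ids],
                       fold_hyper)
    probs <- predict(model, .painted_volumes(matrices, test_ids, ref, seed_roi, atlas))
    pred <- predicted_labels(probs)
    accuracies[f] <- mean(pred == labels[test_ids])
    predictions[[f]] <- data.frame(subject_id = test_ids, fold = f,
                                   truth = as.integer(labels[test_ids]),
                                   predicted = pred, stringsAsFactors = FALSE)
  }
  list(accuracies = accuracies,
       predictions = do.call(rbind, predictions),
       reference_ids = reference_ids)
}

#' Full per-seed-ROI cross-validation report
#'
#' Runs [run_seed_roi_cv()] for every seed ROI and aggregates per-ROI
#' per-fold test accuracies, their mean, the pooled-prediction accuracy
#' (fraction correct over all test predictions; identical to the fold mean
#' only at equal fold sizes), the t-based 95% confidence interval, and the
#' threshold/reliability flags.
#'
#' @inheritParams run_seed_roi_cv
#' @param seed_rois ROI indices to evaluate (default: all atlas labels).
#' @param threshold Accuracy threshold for the flags (default 0.75; strict).
#' @param level Confidence level (default 0.95).
#' @param verbose Print one line per ROI.
#' @return List with `report` (data frame, class `roi_accuracy_report`
#'   attached: roi_label, fold accuracies, mean_accuracy, pooled_accuracy,
#'   ci_low, ci_high, above_threshold, reliable), `predictions` (long data
#'   frame of all test predictions), and `votes` (subject x ROI matrix of
#'   predicted labels for ensemble polling).
#' @export
run_full_cv <- function(matrices, manifest, folds, atlas, spec,
                        hyper = train_hyper(),
                        seed_rois = seq_len(atlas$n_rois),
                        normalization = c("fold", "global"),
                        threshold = 0.75, level = 0.95, verbose = FALSE) {
  normalization <- match.arg(normalization)
  seed_rois <- as.integer(seed_rois)
  rows <- list()
  all_pred <- list()
  votes <- matrix(NA_integer_, nrow(manifest), length(seed_rois),
                  dimnames = list(manifest$subject_id, seed_rois))
  for (j in seq_along(seed_rois)) {
    roi <- seed_rois[j]
    res <- run_seed_roi_cv(matrices, manifest, folds, roi, atlas, spec,
                           hyper, normalization)
    ci <- accuracy_ci(res$accuracies, level)
    acc_row <- as.list(stats::setNames(
      res$accuracies, sprintf("fold%d_accuracy", seq_along(res$accuracies))))
    rows[[j]] <- data.frame(
      roi_label = roi, acc_row,
      mean_accuracy = ci[["mean"]],
      pooled_accuracy = mean(res$predictions$predicted == res$predictions$truth),
      ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
      above_threshold = ci[["mean"]] > threshold,
      reliable = all(res$accuracies > threshold),
      stringsAsFactors = FALSE)
    res$predictions$roi_label <- roi
    all_pred[[j]] <- res$predictions
    votes[res$predictions$subject_id, j] <- res$predictions$predicted
    if (verbose)
      message(sprintf("seed ROI %d: mean accuracy %.3f", roi, ci[["mean"]]))
  }
  report <- do.call(rbind, rows)
  class(report) <- c("roi_accuracy_report", class(report))
  list(report = report, predictions = do.call(rbind, all_pred), votes = votes)
}

#' Subject-level ensemble labels from a vote matrix
#'
#' @param votes Subject x ROI matrix of 0/1 predicted labels (as returned by
#'   [run_full_cv()]).
#' @return Named integer vector of majority-vote labels per subject.
#' @export
ensemble_labels <- function(votes) {
  apply(votes, 1L, ensemble_predict)
}

#' Confusion matrix of predictions
#'
#' @param truth,predicted Integer 0/1 vectors.
#' @return 2 x 2 table (rows = truth, cols = predicted).
#' @export
confusion_matrix <- function(truth, predicted) {
  table(truth = factor(truth, levels = 0:1),
        predicted = factor(predicted, levels = 0:1))
}
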