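# Shared fixtures and independent oracles.

# Brute-force template-match counts by explicit double loop (the O(T^2)
# oracle): counts over the shared N - m start-position range.
brute_cse_counts <- function(x, y, m, r) {
  ntx <- length(x) - m
  nty <- length(y) - m
  a <- 0L
  b <- 0L
  for (i in seq_len(ntx)) {
    for (j in seq_len(nty)) {
      if (max(abs(x[i:(i + m - 1L)] - y[j:(j + m - 1L)])) < r) b <- b + 1L
      if (max(abs(x[i:(i + m)] - y[j:(j + m)])) < r) a <- a + 1L
    }
  }
  c(a = a, b = b)
}

brute_cse_value <- function(x, y, m = 2L, r = 0.6) {
  cnt <- brute_cse_counts(x, y, m, r)
  nt2 <- as.numeric(length(x) - m) * (length(y) - m)
  if (cnt["b"] == 0L) return(NA_real_)
  if (cnt["a"] == 0L) return(-log(1 / nt2))
  unname(-log(cnt["a"] / cnt["b"]))
}

# Small random subject for entropy / preprocessing tests.
toy_timeseries <- function(n_rois = 3L, n_t = 40L, seed = 1L, tr = 2) {
  set.seed(seed)
  roi_timeseries(matrix(rnorm(n_rois * n_t), n_rois, n_t), tr_seconds = tr,
                 subject_id = sprintf("toy-%d", seed))
}

# Tiny labelled blob volumes for classifier sanity tests: class 1 volumes
# carry a positive box in one corner, class 0 in the other, plus noise.
blob_volumes <- function(n_per_class, dims = c(16L, 16L, 16L), seed = 1L,
                         amplitude = 2) {
  set.seed(seed)
  vols <- list()
  labels <- integer(0)
  for (cls in 0:1) {
    for (i in seq_len(n_per_class)) {
      v <- array(rnorm(prod(dims), sd = 0.5), dim = dims)
      if (cls == 0L) v[2:6, 2:6, 2:6] <- v[2:6, 2:6, 2:6] + amplitude
      else v[10:14, 10:14, 10:14] <- v[10:14, 10:14, 10:14] + amplitude
      vols[[length(vols) + 1L]] <- v
      labels <- c(labels, cls)
    }
  }
  list(volumes = vols, labels = labels)
}

# Small simulated cohort + raw CSE matrices used by several suites.
small_cohort_fixture <- function() {
  cfg <- sim_config(n_rois = 4L, n_timepoints = 60L, effect_rois = c(1L, 2L),
                    coupling_ns = 0, coupling_s = 0.8,
                    group_sizes = c(6L, 3L, 3L), seed = 5L)
  cohort <- simulate_cohort(cfg)
  matrices <- lapply(cohort$timeseries, compute_cse_matrix)
  list(config = cfg, manifest = cohort$manifest,
       timeseries = cohort$timeseries, matrices = matrices)
}
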