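test_that("make_toy_atlas covers every label, keeps background, and is seeded", {
  a <- make_toy_atlas(c(4, 4, 4), 2, seed = 1)
  counts <- table(a$data)
  expect_true(all(c("1", "2") %in% names(counts)))
  expect_gte(counts[["1"]], 1)
  expect_gte(counts[["2"]], 1)
  expect_true(any(a$data == 0L))
  expect_error(make_toy_atlas(c(1, 1, 1), 2), "cannot hold")
  b1 <- make_toy_atlas(c(24, 24, 24), 20, seed = 7)
  b2 <- make_toy_atlas(c(24, 24, 24), 20, seed = 7)
  expect_identical(b1$data, b2$data)
  expect_identical(sort(unique(as.integer(b1$data[b1$data > 0]))), 1:20)
  # labels form contiguous blocks: each label's bounding box contains only it
  for (lab in c(3L, 11L)) {
    idx <- which(b1$data == lab, arr.ind = TRUE)
    box <- b1$data[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
                   min(idx[, 3]):max(idx[, 3])]
    expect_true(all(box == lab))
  }
})

test_that("make_mni_grid_atlas uses the standard 2-mm grid", {
  a <- make_mni_grid_atlas(90, seed = 1)
  expect_identical(dim(a$data), c(91L, 109L, 91L))
  expect_identical(sort(unique(as.integer(a$data[a$data > 0]))), 1:90)
  expect_equal(abs(det(a$affine[1:3, 1:3])), 8)  # 2 mm isotropic voxels
  single <- make_mni_grid_atlas(1, seed = 2)
  expect_true(any(single$data == 1L))
  expect_identical(make_mni_grid_atlas(90, seed = 1)$data, a$data)
})

test_that("simulated series are reproducible and band-limited", {
  cfg <- sim_config(n_rois = 5, n_timepoints = 180, group_sizes = c(2, 1, 1))
  a <- simulate_subject_timeseries("NS", cfg, subject_seed = 3)
  b <- simulate_subject_timeseries("NS", cfg, subject_seed = 3)
  expect_identical(a$values, b$values)
  expect_identical(dim(a$values), c(5L, 180L))
  # discrete Fourier decomposition: out-of-band power < 1% of total
  freqs <- seq(0, 179) / (180 * 2)
  freqs <- pmin(freqs, 1 / 2 - freqs)
  in_band <- freqs >= 0.01 & freqs <= 0.08
  for (i in 1:5) {
    p <- Mod(fft(a$values[i, ]))^2
    expect_lt(sum(p[!in_band]) / sum(p), 0.01)
  }
})

test_that("coupling induces cross-correlation only in effect ROIs", {
  cfg0 <- sim_config(n_rois = 4, effect_rois = c(1, 2), coupling_ns = 0,
                     coupling_s = 0, group_sizes = c(1, 1, 1), seed = 2)
  null_corrs <- vapply(1:200, function(i) {
    ts <- simulate_subject_timeseries("SI", cfg0, subject_seed = 5000 + i)
    cor(ts$values[1, ], ts$values[2, ])
  }, numeric(1))
  expect_lt(abs(mean(null_corrs)), 0.05)
  crit <- quantile(abs(null_corrs), 0.975)
  cfg9 <- sim_config(n_rois = 4, effect_rois = c(1, 2), coupling_ns = 0,
                     coupling_s = 0.9, group_sizes = c(1, 1, 1), seed = 2)
  hit <- vapply(1:20, function(i) {
    ts <- simulate_subject_timeseries("SI", cfg9, subject_seed = 7000 + i)
    abs(cor(ts$values[1, ], ts$values[2, ])) > crit
  }, logical(1))
  expect_gt(mean(hit), 0.9)
  # NS subjects with coupling_ns = 0 stay uncoupled under the same config
  ns <- simulate_subject_timeseries("NS", cfg9, subject_seed = 7000)
  expect_lt(abs(cor(ns$values[1, ], ns$values[2, ])), crit + 0.2)
})

test_that("simulate_cohort produces the configured cohort deterministically", {
  cohort <- simulate_cohort(sim_config(n_rois = 3, n_timepoints = 30,
                                       group_sizes = c(2, 1, 1), seed = 4))
  expect_identical(nrow(cohort$manifest), 4L)
  expect_identical(sum(cohort$manifest$binary_target == 0), 2L)
  expect_identical(sum(cohort$manifest$binary_target == 1), 2L)
  expect_identical(cohort$manifest$binary_target,
                   as.integer(cohort$manifest$group != "NS"))
  expect_false(anyDuplicated(cohort$manifest$subject_id) > 0)
  again <- simulate_cohort(sim_config(n_rois = 3, n_timepoints = 30,
                                      group_sizes = c(2, 1, 1), seed = 4))
  expect_identical(cohort$manifest, again$manifest)
  expect_identical(cohort$timeseries[[4]]$values, again$timeseries[[4]]$values)
})

test_that("default cohort composition matches the intended clinical cohort", {
  cfg <- sim_config()
  expect_identical(unname(cfg$group_sizes), c(35L, 26L, 22L))
  expect_identical(cfg$n_rois, 90L)
  expect_identical(cfg$n_timepoints, 180L)
  expect_equal(cfg$tr_seconds, 2)
  groups <- rep(c("NS", "SI", "SA"), times = cfg$group_sizes)
  expect_identical(length(groups), 83L)
  expect_identical(sum(groups == "NS"), 35L)
  expect_identical(sum(groups != "NS"), 48L)
})

test_that("simulate_motion_params marks exactly the requested outliers", {
  m <- simulate_motion_params(10, outlier_indices = 5, seed = 1)
  over <- apply(abs(m) > 2, 2, any)
  expect_identical(which(over), 5L)
  clean <- simulate_motion_params(10, seed = 1)
  expect_false(any(abs(clean) > 2))
  expect_identical(simulate_motion_params(10, outlier_indices = 5, seed = 3),
                   simulate_motion_params(10, outlier_indices = 5, seed = 3))
  expect_error(simulate_motion_params(10, outlier_indices = 11), "1..T")
})

test_that("timeseries_to_volume4d paints rows uniformly for extraction", {
  atlas <- make_toy_atlas(c(6, 6, 6), 3, seed = 2)
  ts <- toy_timeseries(n_rois = 3, n_t = 12, seed = 6)
  vol <- timeseries_to_volume4d(ts, atlas)
  back <- extract_roi_timeseries(vol, atlas)
  expect_equal(unname(back$values), unname(ts$values), tolerance = 1e-12)
})
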