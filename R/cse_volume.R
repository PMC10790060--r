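#' Entrywise reference statistics of CSE matrices
#'
#' Computes the entrywise mean and sample standard deviation (n - 1
#' denominator) of the raw CSE matrices of the reference subjects — the
#' non-suicidal group in the intended analysis — for later centering and
#' scaling of every subject's matrix.
#'
#' @param matrices List of `cse_matrix` objects (same R), named or carrying
#'   `subject_id` fields.
#' @param reference_ids Subject ids to use as the reference group (>= 2).
#' @return Object of class `reference_stats`: `mean_matrix`, `sd_matrix`,
#'   `n_reference`, `reference_ids`.
#' @export
fit_reference_stats <- function(matrices, reference_ids) {
  if (!length(reference_ids)) stop("reference_ids must be nonempty")
  ids <- vapply(matrices, function(m) m$subject_id, character(1))
  missing <- setdiff(reference_ids, ids)
  if (length(missing))
    stop("matrices missing for reference subjects: ", paste(missing, collapse = ", "))
  ref <- matrices[match(reference_ids, ids)]
  if (length(ref) < 2L) stop("need at least 2 reference subjects to estimate an SD")
  dims <- dim(ref[[1L]]$values)
  stack <- vapply(ref, function(m) {
    if (!all(dim(m$values) == dims)) stop("reference matrices differ in size")
    m$values
  }, matrix(0, dims[1L], dims[2L]))
  mean_matrix <- apply(stack, c(1L, 2L), mean)
  sd_matrix <- apply(stack, c(1L, 2L), stats::sd)
  structure(list(mean_matrix = mean_matrix, sd_matrix = sd_matrix,
                 n_reference = length(ref),
                 reference_ids = as.character(reference_ids)),
            class = "reference_stats")
}

#' Center and scale a CSE matrix against reference statistics
#'
#' Entrywise z-scoring: `(raw - mean) / sd`. Entries with zero reference SD
#' are set to 0 (the centered value coincides with the reference mean there,
#' and 0 keeps the matrix uninformative rather than infinite). Undefined raw
#' entries propagate as 0 under the capped policy upstream; any remaining
#' `NA` stays `NA`.
#'
#' @param raw A `cse_matrix`.
#' @param stats A `reference_stats` of matching shape.
#' @return Object of class `normalized_cse_matrix` with fields `subject_id`,
#'   `values`, `reference` (provenance: reference size and ids hash).
#' @export
normalize_cse_matrix <- function(raw, stats) {
  if (!all(dim(raw$values) == dim(stats$mean_matrix)))
    stop("matrix shape does not match reference statistics")
  z <- (raw$values - stats$mean_matrix) / stats$sd_matrix
  z[stats$sd_matrix == 0] <- 0
  structure(list(subject_id = raw$subject_id, values = z,
                 reference = list(n_reference = stats$n_reference,
                                  reference_ids = stats$reference_ids)),
            class = "normalized_cse_matrix")
}

#' CSE volume seeded at one ROI
#'
#' 3D image in which every voxel of atlas region k carries the normalized
#' CSE between the seed region and region k; background voxels carry 0
#' (the reference mean on the z scale).
#'
#' @param matrix A `normalized_cse_matrix` (or plain R x R matrix).
#' @param seed_roi Seed region index (must be an atlas label).
#' @param atlas An `atlas_volume` with `n_rois` equal to R.
#' @return Object of class `cse_volume`: `values` (3D array), `seed_roi`,
#'   `affine`.
#' @export
paint_cse_volume <- function(matrix, seed_roi, atlas) {
  stopifnot(inherits(atlas, "atlas_volume"))
  vals <- if (inherits(matrix, "normalized_cse_matrix")) matrix$values else matrix
  r_ <- nrow(vals)
  if (r_ != atlas$n_rois)
    stop(sprintf("matrix has %d ROIs but atlas has %d labels", r_, atlas$n_rois))
  seed_roi <- as.integer(seed_roi)
  if (seed_roi < 1L || seed_roi > r_) stop("seed_roi is not an atlas label")
  row <- vals[seed_roi, ]
  lookup <- c(0, row)  # background -> 0
  painted <- array(lookup[as.integer(atlas$data) + 1L], dim = dim(atlas$data))
  structure(list(values = painted, seed_roi = seed_roi, affine = atlas$affine),
            class = "cse_volume")
}

#' All seed-ROI CSE volumes for one subject
#'
#' @param matrix A `normalized_cse_matrix`.
#' @param atlas An `atlas_volume`.
#' @return List of R `cse_volume` objects, seeded at ROIs 1..R.
#' @export
build_subject_volumes <- function(matrix, atlas) {
  lapply(seq_len(atlas$n_rois), function(k) paint_cse_volume(matrix, k, atlas))
}

#' Read ROI means back out of a painted volume
#'
#' Inverse of [paint_cse_volume()] for checking the paint/readback
#' round trip: returns, for each label, the mean voxel value inside that
#' region.
#'
#' @param volume A `cse_volume` (or 3D array).
#' @param atlas The `atlas_volume` used for painting.
#' @return Numeric vector of length `n_rois`.
#' @export
readback_roi_values <- function(volume, atlas) {
  vals <- if (inherits(volume, "cse_volume")) volume$values else volume
  vapply(seq_len(atlas$n_rois),
         function(k) mean(vals[atlas$data == k]), numeric(1))
}
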