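# Tabular and volumetric I/O. All tabular data are TSV, volumes are NIfTI,
# provenance is JSON; every writer has a reader that round-trips exactly.

#' Write / read an ROI time series as TSV
#'
#' Layout: first column `roi_label`, remaining columns one per timepoint
#' headed by the timepoint index; one row per ROI. TR is carried in a
#' `# tr_seconds` comment line.
#'
#' @param ts A `roi_timeseries`.
#' @param path Output file.
#' @return `path` invisibly (writer); a `roi_timeseries` (reader).
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds=%.17g subject_id=%s",
                     ts$tr_seconds, ts$subject_id), con)
  df <- data.frame(roi_label = ts$roi_labels, ts$values, check.names = FALSE)
  colnames(df) <- c("roi_label", seq_len(ncol(ts$values)))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  tr <- as.numeric(sub(".*tr_seconds=([0-9.eE+-]+).*", "\\1", header))
  sid <- sub(".*subject_id=(\\S+).*", "\\1", header)
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  roi_timeseries(as.matrix(df[, -1L, drop = FALSE]),
                 roi_labels = df$roi_label, tr_seconds = tr, subject_id = sid)
}

#' Write / read a cohort manifest as TSV
#' @param manifest Data frame (`subject_id`, `group`, `binary_target`).
#' @param path File path.
#' @export
write_manifest_tsv <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_tsv
#' @export
read_manifest_tsv <- function(path) {
  utils::read.delim(path, colClasses = c("character", "character", "integer"))
}

#' Write / read a motion trace as TSV (6 named columns, one row per frame)
#' @param motion 6 x T matrix.
#' @param path File path.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(t(motion), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  t(as.matrix(utils::read.delim(path)))
}

#' Write / read a CSE matrix as TSV with a JSON parameter sidecar
#'
#' The TSV holds the R x R values with ROI-label header; the sidecar
#' (`<path>.json`) records subject id, matching parameters and the number of
#' undefined entries.
#'
#' @param mat A `cse_matrix`.
#' @param path TSV path.
#' @export
write_cse_matrix_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "cse_matrix"))
  df <- as.data.frame(mat$values, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(subject_id = mat$subject_id,
                  m = mat$params$m, r = mat$params$r,
                  undefined_policy = mat$params$undefined_policy,
                  standardize = mat$params$standardize,
                  n_undefined = sum(mat$undefined_mask),
                  undefined_entries =
                    as.data.frame(which(mat$undefined_mask, arr.ind = TRUE)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cse_matrix_tsv
#' @export
read_cse_matrix_tsv <- function(path) {
  values <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  undef <- matrix(FALSE, nrow(values), ncol(values))
  for (e in meta$undefined_entries)
    undef[e$row, e$col] <- TRUE
  dimnames(values) <- list(colnames(values), colnames(values))
  structure(list(subject_id = meta$subject_id, values = values,
                 params = entropy_params(meta$m, meta$r, meta$undefined_policy,
                                         meta$standardize),
                 undefined_mask = undef),
            class = "cse_matrix")
}

#' Write / read an atlas as NIfTI
#' @param atlas An `atlas_volume`.
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_volume"))
  img <- RNifti::asNifti(atlas$data)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.integer(round(img)), dim = dim(img))
  atlas_volume(data, affine = unclass(RNifti::xform(img)), n_rois = max(data))
}

#' Write a painted CSE volume as NIfTI (float data, atlas affine)
#' @param volume A `cse_volume`.
#' @param path NIfTI path.
#' @export
write_cse_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "cse_volume"))
  img <- RNifti::asNifti(volume$values)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a per-ROI accuracy report as TSV
#' @param report The `report` data frame from [run_full_cv()].
#' @param path TSV path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  report <- utils::read.delim(path)
  class(report) <- c("roi_accuracy_report", class(report))
  report
}
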