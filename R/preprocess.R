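#' ROI time-series container
#'
#' Per-subject matrix of mean ROI signals: one row per region of interest,
#' one column per acquisition volume, with the sampling interval (TR)
#' attached.
#'
#' @param values R x T numeric matrix (all finite).
#' @param roi_labels Unique positive integer labels, one per row.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param subject_id Subject identifier string.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, roi_labels = seq_len(nrow(values)),
                           tr_seconds = 2, subject_id = "subject") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("time-series values must all be finite")
  if (nrow(values) < 2L) stop("need at least 2 ROIs")
  if (ncol(values) < 10L) stop("need at least 10 timepoints")
  roi_labels <- as.integer(roi_labels)
  if (anyDuplicated(roi_labels) || any(roi_labels < 1L))
    stop("roi_labels must be unique positive integers")
  if (length(roi_labels) != nrow(values))
    stop("one roi label per matrix row required")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  rownames(values) <- roi_labels
  structure(list(subject_id = as.character(subject_id), values = values,
                 roi_labels = roi_labels, tr_seconds = as.numeric(tr_seconds)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s: %d ROIs x %d timepoints, TR %gs\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

.replace_values <- function(ts, values) {
  ts$values <- values
  rownames(ts$values) <- ts$roi_labels
  ts
}

#' Frame-censoring mask from motion parameters
#'
#' Flags acquisition frames whose head motion exceeds the displacement or
#' rotation threshold: any of the three translations above
#' `translation_threshold_mm` (in absolute value) or any of the three
#' rotation angles above `rotation_threshold_deg`. By default all three
#' translation axes are screened (a conservative reading of an axial
#' displacement criterion); set `axial_only = TRUE` to restrict the
#' translation check to the third (z) axis.
#'
#' @param motion 6 x T numeric matrix: rows 1-3 translations (mm),
#'   rows 4-6 rotations (degrees).
#' @param translation_threshold_mm,rotation_threshold_deg Censoring
#'   thresholds; defaults 2 mm and 2 degrees.
#' @param axial_only Screen only the z translation axis.
#' @return Logical keep-mask of length T (`FALSE` = censored frame).
#' @export
motion_censor <- function(motion, translation_threshold_mm = 2,
                          rotation_threshold_deg = 2, axial_only = FALSE) {
  motion <- as.matrix(motion)
  if (nrow(motion) != 6L) stop("motion trace must have 6 rows (3 translations, 3 rotations)")
  trans <- if (axial_only) motion[3L, , drop = FALSE] else motion[1:3, , drop = FALSE]
  rot <- motion[4:6, , drop = FALSE]
  bad <- apply(abs(trans) > translation_threshold_mm, 2L, any) |
    apply(abs(rot) > rotation_threshold_deg, 2L, any)
  !bad
}

#' Apply a frame keep-mask to an ROI time series
#'
#' Censored frames are dropped from every ROI row (no interpolation);
#' downstream entropy estimation uses the shortened series.
#'
#' @param ts A `roi_timeseries`.
#' @param keep Logical mask of length T.
#' @return Shortened `roi_timeseries`.
#' @export
apply_censor <- function(ts, keep) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (length(keep) != ncol(ts$values)) stop("mask length must equal T")
  .replace_values(ts, ts$values[, keep, drop = FALSE])
}

#' Average voxel time series within atlas regions
#'
#' Row k of the output is the arithmetic mean, at each timepoint, of all
#' voxels carrying atlas label k; rows are ordered by ascending label.
#'
#' @param volume4d 4D numeric array (X x Y x Z x T).
#' @param atlas An [atlas_volume] with matching spatial extents.
#' @param tr_seconds,subject_id Metadata for the returned series.
#' @return A `roi_timeseries` with one row per atlas label.
#' @export
extract_roi_timeseries <- function(volume4d, atlas, tr_seconds = 2,
                                   subject_id = "subject") {
  stopifnot(inherits(atlas, "atlas_volume"))
  d <- dim(volume4d)
  if (length(d) != 4L || !all(d[1:3] == dim(atlas$data)))
    stop("4D volume extents do not match the atlas grid")
  labels <- sort(unique(as.integer(atlas$data[atlas$data > 0L])))
  expected <- seq_len(atlas$n_rois)
  if (!all(expected %in% labels))
    stop("atlas labels with zero voxels: ",
         paste(setdiff(expected, labels), collapse = ", "))
  n_vox <- prod(d[1:3])
  flat <- matrix(volume4d, nrow = n_vox, ncol = d[4L])
  lab <- as.integer(atlas$data)
  keep <- lab > 0L
  sums <- rowsum(flat[keep, , drop = FALSE], lab[keep])
  counts <- as.vector(table(lab[keep]))
  roi_timeseries(sums / counts, roi_labels = labels,
                 tr_seconds = tr_seconds, subject_id = subject_id)
}

#' Remove the least-squares linear trend from each ROI series
#'
#' @param ts A `roi_timeseries` with T >= 3.
#' @return Detrended `roi_timeseries` (per-row residual of intercept+slope fit).
#' @export
detrend_timeseries <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- ncol(ts$values)
  if (n < 3L) stop("detrending needs T >= 3")
  x <- cbind(1, seq_len(n))
  coef <- solve(crossprod(x), crossprod(x, t(ts$values)))
  .replace_values(ts, ts$values - t(x %*% coef))
}

#' Ideal band-pass filter via frequency-domain masking
#'
#' Removes all discrete Fourier components with frequency outside
#' `[f_low, f_high]` (band edges inclusive), including the DC term when
#' `f_low > 0`. The rectangular spectral mask reproduces the behavior of the
#' resting-state toolboxes commonly used for this step; series length is
#' preserved.
#'
#' @param ts A `roi_timeseries`.
#' @param f_low,f_high Pass-band edges in Hz; defaults 0.01 and 0.08.
#' @return Filtered `roi_timeseries`.
#' @export
bandpass_timeseries <- function(ts, f_low = 0.01, f_high = 0.08) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(f_low < f_high && f_high < nyq))
    stop(sprintf("band [%g, %g] Hz must satisfy f_low < f_high < Nyquist (%g Hz)",
                 f_low, f_high, nyq))
  .replace_values(ts, bandpass_matrix(ts$values, ts$tr_seconds, f_low, f_high))
}

# Row-wise ideal band-pass of a numeric matrix (rows = series).
bandpass_matrix <- function(values, tr_seconds, f_low, f_high) {
  n <- ncol(values)
  freqs <- seq(0L, n - 1L) / (n * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)  # two-sided spectrum
  mask <- freqs >= f_low & freqs <= f_high
  out <- t(apply(values, 1L, function(row) {
    sp <- stats::fft(row)
    sp[!mask] <- 0
    Re(stats::fft(sp, inverse = TRUE)) / n
  }))
  dimnames(out) <- dimnames(values)
  out
}

#' Regress nuisance signals out of each ROI series
#'
#' Each ROI row is replaced by the residual of an ordinary least-squares
#' regression on the confound rows plus an intercept. A rank-deficient design
#' is handled by the minimum-norm (pseudoinverse) solution, so duplicated or
#' collinear confounds do not fail. With an empty confound set the operation
#' reduces to per-row mean removal.
#'
#' @param ts A `roi_timeseries`.
#' @param confounds C x T numeric matrix (may have zero rows).
#' @return Residualized `roi_timeseries`.
#' @export
regress_nuisance <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- ncol(ts$values)
  if (is.null(confounds)) confounds <- matrix(numeric(0), nrow = 0L, ncol = n)
  confounds <- as.matrix(confounds)
  if (ncol(confounds) != n) stop("confound rows must have length T")
  design <- cbind(1, t(confounds))
  sv <- svd(design)
  pos <- sv$d > max(dim(design)) * .Machine$double.eps * max(sv$d)
  proj <- sv$u[, pos, drop = FALSE]
  fitted <- proj %*% crossprod(proj, t(ts$values))
  .replace_values(ts, ts$values - t(fitted))
}

#' Full time-series cleaning chain
#'
#' Applies the fixed pipeline order: frame censoring, detrending, band-pass
#' filtering, nuisance regression. ROI extraction (when starting from 4D
#' voxel data) is done beforehand with [extract_roi_timeseries()].
#'
#' @param ts A `roi_timeseries`.
#' @param motion Optional 6 x T motion trace for censoring.
#' @param confounds Optional C x T confound matrix.
#' @param f_low,f_high Band-pass edges (Hz).
#' @param ... Passed to [motion_censor()].
#' @return Cleaned `roi_timeseries`.
#' @export
preprocess_timeseries <- function(ts, motion = NULL, confounds = NULL,
                                  f_low = 0.01, f_high = 0.08, ...) {
  if (!is.null(motion)) {
    keep <- motion_censor(motion, ...)
    ts <- apply_censor(ts, keep)
    if (!is.null(confounds)) confounds <- as.matrix(confounds)[, keep, drop = FALSE]
  }
  ts <- detrend_timeseries(ts)
  ts <- bandpass_timeseries(ts, f_low, f_high)
  regress_nuisance(ts, confounds)
}
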