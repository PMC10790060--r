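#' Entropy matching parameters
#'
#' Bundle of the template-matching parameters used by cross-sample entropy:
#' embedding dimension `m`, Chebyshev tolerance `r` (in SD units of the
#' standardized series), and the policy applied when a match count is zero.
#'
#' @param m Template (embedding) length; default 2.
#' @param r Match tolerance; default 0.6. With `standardize = TRUE` the
#'   tolerance is expressed in standard-deviation units of each series.
#' @param undefined_policy One of `"cap"` (replace `-log(0)` by the largest
#'   value observable with the given template count, `-log(1/n_pairs)`) or
#'   `"missing"` (return `NA` and record the entry in the undefined mask).
#' @param standardize Standardize each series to mean 0, SD 1 before matching
#'   (the usual sample-entropy convention). A raw-units mode
#'   (`standardize = FALSE`) is exposed for sensitivity checks.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r = 0.6, undefined_policy = c("cap", "missing"),
                           standardize = TRUE) {
  m <- as.integer(m)
  undefined_policy <- match.arg(undefined_policy)
  if (m < 1L) stop("template length `m` must be >= 1")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("tolerance `r` must be > 0")
  structure(list(m = m, r = r, undefined_policy = undefined_policy,
                 standardize = isTRUE(standardize)),
            class = "entropy_params")
}

#' Standardize a series to zero mean and unit standard deviation
#'
#' Constant series (zero SD) map to the all-zero series rather than NaN, so
#' that degenerate ROI signals stay finite downstream.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector with mean 0 and sample SD 1 (or all zeros).
#' @export
standardize_series <- function(x) {
  if (length(x) < 2L) stop("series must have length >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Chebyshev (maximum-coordinate) distance between two templates
#'
#' @param u,v Numeric vectors of equal length.
#' @return `max_k |u_k - v_k|`.
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) stop("template length mismatch")
  max(abs(u - v))
}

#' Count cross-series template matches
#'
#' Counts ordered template pairs (i, j) whose length-`l` sub-vectors
#' `x[i..i+l-1]` and `y[j..j+l-1]` lie within Chebyshev distance `< r`
#' (strict inequality). The comparison range defaults to all valid start
#' positions (`N - l + 1` per series) but can be restricted with
#' `n_templates_*`; cross-sample entropy compares both template lengths over
#' the same `N - m` start positions.
#'
#' The counting is vectorized: a T x T Boolean proximity matrix
#' `|x_i - y_j| < r` is AND-combined with its diagonal shifts, which is
#' algebraically identical to the explicit double loop over template pairs.
#'
#' @param x,y Numeric series (already on the scale `r` refers to).
#' @param l Template length.
#' @param r Tolerance.
#' @param n_templates_x,n_templates_y Number of start positions to compare.
#' @return Integer match count.
#' @export
count_matches <- function(x, y, l, r,
                          n_templates_x = length(x) - l + 1L,
                          n_templates_y = length(y) - l + 1L) {
  l <- as.integer(l)
  if (length(x) < l + 1L || length(y) < l + 1L)
    stop("series too short for template length ", l)
  n_templates_x <- as.integer(n_templates_x)
  n_templates_y <- as.integer(n_templates_y)
  if (n_templates_x < 1L || n_templates_y < 1L) stop("no templates to compare")
  if (n_templates_x + l - 1L > length(x) || n_templates_y + l - 1L > length(y))
    stop("template range exceeds series length")
  close_ <- abs(outer(x, y, "-")) < r
  ix <- seq_len(n_templates_x)
  iy <- seq_len(n_templates_y)
  m_ <- close_[ix, iy, drop = FALSE]
  if (l > 1L) {
    for (k in seq_len(l - 1L)) {
      m_ <- m_ & close_[ix + k, iy + k, drop = FALSE]
    }
  }
  sum(m_)
}

#' Cross-sample entropy between two series
#'
#' Cross-sample entropy (CSE) quantifies the asynchrony of two series as
#' `-log(A / B)`, where `B` counts template pairs matching at length `m` and
#' `A` those matching at length `m + 1`, both counted over the same `N - m`
#' template start positions per series (the Richman-Moorman convention, which
#' guarantees `A <= B` and hence CSE >= 0). Lower values mean greater
#' synchrony. Matching uses the Chebyshev distance with strict tolerance
#' `< r`.
#'
#' When no length-`m` pair matches (`B = 0`) the value is undefined and `NA`
#' is returned regardless of policy. When `B > 0` but `A = 0`, the policy
#' decides: `"cap"` substitutes the largest observable value
#' `-log(1 / (n_tx * n_ty))`, `"missing"` returns `NA`.
#'
#' @param x,y Numeric series of length >= m + 2.
#' @param params An [entropy_params()] object.
#' @return Scalar CSE value, or `NA_real_` with attribute `undefined = TRUE`.
#' @export
cross_sample_entropy <- function(x, y, params = entropy_params()) {
  m <- params$m
  if (length(x) < m + 2L || length(y) < m + 2L)
    stop("series must have length >= m + 2")
  if (params$standardize) {
    x <- standardize_series(x)
    y <- standardize_series(y)
  }
  ntx <- length(x) - m
  nty <- length(y) - m
  b_total <- count_matches(x, y, m, params$r, ntx, nty)
  a_total <- count_matches(x, y, m + 1L, params$r, ntx, nty)
  .cse_from_counts(a_total, b_total, ntx, nty, params$undefined_policy)
}

.cse_from_counts <- function(a_total, b_total, ntx, nty, policy) {
  if (b_total == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (a_total == 0L) {
    if (policy == "cap") return(-log(1 / (as.numeric(ntx) * as.numeric(nty))))
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(a_total / b_total)
}

#' Pairwise cross-sample entropy matrix for one subject
#'
#' Computes CSE between every ordered pair of ROI rows of a time-series
#' object, including the self-pairs on the diagonal (the match-count formula
#' applied verbatim to `(x, x)`; set `include_diagonal = FALSE` to leave the
#' diagonal `NA`). The result is symmetric by construction: only the upper
#' triangle is computed and mirrored.
#'
#' @param ts A [roi_timeseries()] object (R x T).
#' @param params An [entropy_params()] object.
#' @param include_diagonal Compute self-pair entries (default `TRUE`).
#' @return An object of class `cse_matrix`: list with `subject_id`, `values`
#'   (R x R, dimnames = ROI labels), `params`, and logical `undefined_mask`.
#' @export
compute_cse_matrix <- function(ts, params = entropy_params(),
                               include_diagonal = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- ts$values
  r_ <- nrow(v)
  n <- ncol(v)
  m <- params$m
  if (n < m + 2L) stop("time series too short for m = ", m)
  rows <- if (params$standardize) t(apply(v, 1L, standardize_series)) else v
  nt <- n - m
  values <- matrix(NA_real_, r_, r_)
  undef <- matrix(FALSE, r_, r_)
  for (i in seq_len(r_)) {
    j0 <- if (include_diagonal) i else i + 1L
    if (j0 > r_) next
    for (j in j0:r_) {
      b_total <- count_matches(rows[i, ], rows[j, ], m, params$r, nt, nt)
      a_total <- count_matches(rows[i, ], rows[j, ], m + 1L, params$r, nt, nt)
      val <- .cse_from_counts(a_total, b_total, nt, nt, params$undefined_policy)
      und <- isTRUE(attr(val, "undefined"))
      values[i, j] <- values[j, i] <- as.numeric(val)
      undef[i, j] <- undef[j, i] <- und
    }
  }
  dimnames(values) <- list(ts$roi_labels, ts$roi_labels)
  structure(list(subject_id = ts$subject_id, values = values,
                 params = params, undefined_mask = undef),
            class = "cse_matrix")
}

#' @export
print.cse_matrix <- function(x, ...) {
  cat(sprintf("<cse_matrix> subject %s: %d x %d (m = %d, r = %g, %d undefined)\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              x$params$m, x$params$r, sum(x$undefined_mask)))
  invisible(x)
}
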