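#' Atlas label volume
#'
#' Integer parcellation grid: voxel value 0 is background, values 1..n_rois
#' are region labels. The affine maps voxel indices (0-based, as in the NIfTI
#' convention) to world coordinates.
#'
#' @param data 3D integer array of labels.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param n_rois Number of region labels.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(data, affine = diag(4), n_rois = max(data)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("atlas data must be a 3D array")
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stop("atlas labels must be >= 0")
  n_rois <- as.integer(n_rois)
  missing <- setdiff(seq_len(n_rois), unique(as.integer(data)))
  if (length(missing))
    stop("atlas labels with zero voxels: ", paste(missing, collapse = ", "))
  structure(list(data = data, affine = affine, n_rois = n_rois),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("<atlas_volume> %s voxels, %d ROIs\n",
              paste(dim(x$data), collapse = " x "), x$n_rois))
  invisible(x)
}

# Split `extent` voxels into `pieces` consecutive runs of near-equal length.
.axis_splits <- function(extent, pieces) {
  sizes <- rep(extent %/% pieces, pieces)
  extra <- extent %% pieces
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = ends - sizes + 1L, end = ends)
}

#' Build a toy block parcellation
#'
#' Partitions the volume into a rectangular grid of cells and labels the
#' interior of the first `n_rois` cells (cell-to-label assignment is shuffled
#' with `seed`). Each label occupies one contiguous block of voxels; a one
#' voxel margin is left unlabeled along each axis where the cell permits, so
#' the volume keeps background voxels. Intended as a stand-in parcellation
#' for pipeline tests.
#'
#' @param shape Integer vector of 3 extents.
#' @param n_rois Number of regions.
#' @param seed RNG seed for the cell shuffle.
#' @param affine Optional voxel-to-world matrix.
#' @return An `atlas_volume`.
#' @export
make_toy_atlas <- function(shape, n_rois, seed = 1L, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive extents")
  n_rois <- as.integer(n_rois)
  if (prod(shape) < n_rois)
    stop(sprintf("volume of %d voxels cannot hold %d ROIs", prod(shape), n_rois))
  # smallest grid of cells (within extents) holding n_rois cells
  pieces <- c(1L, 1L, 1L)
  while (prod(pieces) < n_rois) {
    growable <- which(pieces < shape)
    if (!length(growable)) stop("extents too small for requested ROI count")
    ax <- growable[which.min(pieces[growable] / shape[growable])]
    pieces[ax] <- pieces[ax] + 1L
  }
  splits <- lapply(1:3, function(a) .axis_splits(shape[a], pieces[a]))
  cells <- expand.grid(i = seq_len(pieces[1L]), j = seq_len(pieces[2L]),
                       k = seq_len(pieces[3L]))
  old <- .restore_seed(seed)
  on.exit(old())
  chosen <- sample(nrow(cells), n_rois)
  data <- array(0L, dim = shape)
  for (lab in seq_len(n_rois)) {
    cell <- cells[chosen[lab], ]
    rng <- lapply(1:3, function(a) {
      s <- splits[[a]][cell[[a]], ]
      # leave a 1-voxel background margin where the cell is wider than 1
      if (s["end"] > s["start"]) s["end"] <- s["end"] - 1L
      s["start"]:s["end"]
    })
    data[rng[[1L]], rng[[2L]], rng[[3L]]] <- lab
  }
  atlas_volume(data, affine = affine, n_rois = n_rois)
}

#' Toy parcellation on the standard 2-mm MNI grid
#'
#' Places a block parcellation (see [make_toy_atlas()]) inside the central
#' portion of the 91 x 109 x 91 bounding grid of the MNI152 template at
#' 2 x 2 x 2 mm resolution, with the standard 2-mm affine.
#'
#' @param n_rois Number of regions (>= 1).
#' @param seed RNG seed.
#' @return An `atlas_volume` with extents (91, 109, 91).
#' @export
make_mni_grid_atlas <- function(n_rois, seed = 1L) {
  n_rois <- as.integer(n_rois)
  if (n_rois < 1L) stop("n_rois must be >= 1")
  shape <- c(91L, 109L, 91L)
  affine <- rbind(c(-2, 0, 0, 90), c(0, 2, 0, -126), c(0, 0, 2, -72),
                  c(0, 0, 0, 1))
  # parcellate a central box covering ~60% of each axis, leave the rest background
  lo <- pmax(1L, as.integer(round(shape * 0.2)))
  hi <- as.integer(round(shape * 0.8))
  inner <- make_toy_atlas(hi - lo + 1L, n_rois, seed = seed)
  data <- array(0L, dim = shape)
  data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- inner$data
  atlas_volume(data, affine = affine, n_rois = n_rois)
}

# Run code under a seeded RNG and restore the caller's RNG state afterwards.
.restore_seed <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
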