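#' Binary voxel volume
#'
#' Light container for a 3D boolean occupancy grid, the object whose
#' tortuosity is measured. Indices are conceptually 0-based: the voxel at
#' index (i, j, k) occupies the unit cube \eqn{[i,i+1) \times [j,j+1)
#' \times [k,k+1)}, so crack-boundary vertices of slice contours fall on
#' integer lattice points. Voxels are assumed isotropic; the measure is
#' unit-free.
#'
#' @param grid 3D array; coerced to logical with `grid != 0` unless
#'   already logical.
#' @param spacing isotropic voxel edge length (kept as metadata only;
#'   default 1).
#' @return An object of class `binary_volume` with elements `grid`
#'   (logical 3D array), `shape` (integer triple) and `spacing`.
#' @examples
#' v <- binary_volume(array(1, dim = c(3, 3, 3)))
#' foreground_count(v)
#' @export
binary_volume <- function(grid, spacing = 1) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3-dimensional array")
  if (any(dim(grid) < 1L)) stop("all extents must be >= 1")
  if (!is.logical(grid)) {
    g <- grid != 0
  } else {
    g <- grid
  }
  if (anyNA(g)) stop("grid contains NA after binarization")
  dim(g) <- dim(grid)
  structure(
    list(grid = g, shape = as.integer(dim(g)), spacing = as.numeric(spacing)),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf(
    "<binary_volume %s, %d foreground voxel(s), spacing %g>\n",
    paste(x$shape, collapse = "x"), foreground_count(x), x$spacing
  ))
  invisible(x)
}

#' Number of foreground voxels
#' @param vol a [binary_volume()].
#' @return integer count.
#' @export
foreground_count <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  sum(vol$grid)
}

#' Load a volume from disk and binarize it
#'
#' Reads a NIfTI-1 file (`.nii`, `.nii.gz`) or an R-serialized 3D array
#' (`.rds`) and thresholds it into a [binary_volume()]. The NIfTI
#' affine/orientation is ignored: volumes are treated as abstract voxel
#' grids, so tortuosity values are comparable only within one grid
#' convention.
#'
#' @param path file path.
#' @param threshold intensities strictly greater than this become
#'   foreground (default 0.5).
#' @return a [binary_volume()]; an empty foreground is permitted at load
#'   time (it is rejected later by [tortuosity_3d()]).
#' @export
load_volume <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  arr <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    as.array(RNifti::readNifti(path))
  } else if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    readRDS(path)
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .rds): ", path)
  }
  arr <- drop(as.array(arr))
  if (length(dim(arr)) != 3L)
    stop("volume in ", path, " is not 3-dimensional")
  binary_volume(arr > threshold)
}

#' Write a volume to disk
#'
#' Inverse of [load_volume()]: foreground voxels are written as 1,
#' background as 0, either as NIfTI-1 or as a serialized array.
#'
#' @param vol a [binary_volume()].
#' @param path destination ending in `.nii`, `.nii.gz` or `.rds`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "binary_volume"))
  arr <- array(as.integer(vol$grid), dim = vol$shape)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(arr, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Cut a volume into 2D slices perpendicular to one axis
#'
#' Axis X slices are indexed by the first array coordinate and their 2D
#' masks keep the (second, third) coordinates in that order; analogously
#' Y keeps (first, third) and Z keeps (first, second). This fixed
#' convention makes traced contours reproducible.
#'
#' @param vol a [binary_volume()].
#' @param axis one of `"X"`, `"Y"`, `"Z"`.
#' @return list of slice planes in increasing index order; each is a list
#'   with `axis`, `index` (1-based slice position), `mask` (logical
#'   matrix) and `empty` (no foreground in this slice).
#' @export
extract_slices <- function(vol, axis = c("X", "Y", "Z")) {
  stopifnot(inherits(vol, "binary_volume"))
  axis <- match.arg(axis)
  d <- vol$shape
  n <- switch(axis, X = d[1L], Y = d[2L], Z = d[3L])
  lapply(seq_len(n), function(i) {
    mask <- switch(axis,
      X = vol$grid[i, , , drop = TRUE],
      Y = vol$grid[, i, , drop = TRUE],
      Z = vol$grid[, , i, drop = TRUE]
    )
    # drop = TRUE collapses length-1 extents; restore matrix shape
    if (is.null(dim(mask))) {
      md <- switch(axis,
        X = d[c(2L, 3L)], Y = d[c(1L, 3L)], Z = d[c(1L, 2L)]
      )
      dim(mask) <- md
    }
    list(axis = axis, index = i, mask = mask, empty = !any(mask))
  })
}

# Offsets of the discrete ball {o : ||o||_2 <= radius}, as an
# (2r+1)^3 logical array centred at index r+1.
ball_kernel <- function(radius) {
  r <- as.integer(radius)
  ax <- (-r):r
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  d2 <= radius^2
}

# Circular convolution of a 0/1 array with a kernel centred at the
# origin, via FFT; returns integer counts (exact after rounding: counts
# are small integers and the FFT error is ~1e-9 relative).
conv_counts <- function(arr, kern_fft) {
  co <- Re(stats::fft(stats::fft(arr) * kern_fft, inverse = TRUE)) / length(arr)
  round(co)
}

#' Morphological closing with a discrete ball
#'
#' Dilation followed by erosion of the foreground by the structuring
#' element \eqn{B = \{o : \lVert o\rVert_2 \le r\}}: fills gaps and
#' concavities narrower than the ball, smoothing rough surface features.
#' The grid is zero-padded internally by the ball radius and cropped
#' back, so dilation can never truncate at the array border; the output
#' shape equals the input shape.
#'
#' @param vol a [binary_volume()].
#' @param radius positive integer ball radius (voxels).
#' @return a closed [binary_volume()]; the foreground is always a
#'   superset of the input foreground (closing is extensive).
#' @export
morphological_closing <- function(vol, radius) {
  stopifnot(inherits(vol, "binary_volume"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1")
  r <- radius
  d <- vol$shape
  pd <- d + 2L * r
  a <- array(0, dim = pd)
  a[r + seq_len(d[1L]), r + seq_len(d[2L]), r + seq_len(d[3L])] <-
    as.numeric(vol$grid)

  kern <- ball_kernel(r)
  nb <- sum(kern)
  # place kernel wrapped around the origin of the padded array
  kw <- array(0, dim = pd)
  idx <- lapply(pd, function(n) ((((-r):r) %% n) + 1L))
  kw[idx[[1L]], idx[[2L]], idx[[3L]]] <- as.numeric(kern)
  kf <- stats::fft(kw)

  dil <- conv_counts(a, kf) >= 1
  ero <- conv_counts(array(as.numeric(dil), dim = pd), kf) >= nb
  out <- ero[r + seq_len(d[1L]), r + seq_len(d[2L]), r + seq_len(d[3L])]
  binary_volume(array(out, dim = d), spacing = vol$spacing)
}
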