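#' Sub-voxel center offset for a generation angle
#'
#' A digitized sphere is rotation-invariant as a solid, so "generating a
#' sphere at an angle" can only change how the continuous surface falls
#' across the voxel grid. The generation angle is therefore mapped to a
#' sub-voxel offset of the sphere center, `frac(angle/360 * m)` with
#' fixed irrational multipliers `m = (golden ratio, sqrt 2, sqrt 3)`, so
#' that sweeping the angle exercises the rasterization phase in all
#' three axes the way a grid rotation would, deterministically.
#'
#' @param angle generation angle in degrees, any real.
#' @return numeric offset triple, each component in `[0, 1)`.
#' @export
angle_offset <- function(angle) {
  mult <- c((1 + sqrt(5)) / 2, sqrt(2), sqrt(3))
  (angle / 360 * mult) %% 1
}

# shared grid builder: voxel centers at integer coordinates 1..side
shape_grid <- function(radius_extent, margin) {
  side <- as.integer(ceiling(2 * radius_extent)) + 2L * as.integer(margin) + 1L
  list(side = side, center = (side + 1) / 2)
}

#' Voxelized sphere
#'
#' Rasterizes a solid sphere: a voxel is foreground iff the Euclidean
#' distance from its center to the sphere center (grid center plus the
#' sub-voxel `center_offset`) is at most `radius`. The grid side is
#' `ceiling(2*radius) + 2*margin + 1`, so the object never touches the
#' array border for `margin >= 1`.
#'
#' @param radius sphere radius in voxels, `>= 1`.
#' @param angle generation angle in degrees, converted to a sub-voxel
#'   center offset by [angle_offset()]; ignored when `center_offset` is
#'   given explicitly.
#' @param margin empty voxel layers around the bounding box (default 2).
#' @param center_offset optional explicit offset triple in `[0, 1)^3`.
#' @return a [binary_volume()].
#' @examples
#' foreground_count(make_sphere(1))   # center voxel + 6 face neighbors
#' @export
make_sphere <- function(radius, angle = 0, margin = 2,
                        center_offset = NULL) {
  if (radius < 1) stop("`radius` must be >= 1")
  if (is.null(center_offset)) center_offset <- angle_offset(angle)
  stopifnot(length(center_offset) == 3, all(center_offset >= 0),
            all(center_offset < 1))
  g <- shape_grid(radius, margin)
  ctr <- g$center + center_offset
  ax <- seq_len(g$side)
  d2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, `+`),
              (ax - ctr[3])^2, `+`)
  binary_volume(d2 <= radius^2)
}

#' Voxelized axis-aligned solid cube
#'
#' @param side cube edge length in voxels, positive integer.
#' @param margin empty voxel layers around the cube (default 2).
#' @return a [binary_volume()] with exactly `side^3` foreground voxels.
#' @export
make_cube <- function(side, margin = 2) {
  side <- as.integer(side)
  if (side < 1L) stop("`side` must be >= 1")
  margin <- as.integer(margin)
  n <- side + 2L * margin
  g <- array(FALSE, dim = c(n, n, n))
  idx <- margin + seq_len(side)
  g[idx, idx, idx] <- TRUE
  binary_volume(g)
}

#' Voxelized sphere with sinusoidal surface bumps
#'
#' A gyrified-surface stand-in: a voxel at spherical coordinates
#' \eqn{(d, \theta, \phi)} about the grid center is foreground iff
#' \eqn{d \le r + A \sin(f\theta)\sin(f\phi)}, where \eqn{\theta} is the
#' polar and \eqn{\phi} the azimuthal angle. With `bump_amplitude = 0`
#' this reduces exactly to [make_sphere()] with zero center offset.
#'
#' @param radius base sphere radius, `>= 1`.
#' @param bump_amplitude bump height in voxels, `>= 0`.
#' @param bump_frequency positive integer angular frequency.
#' @param margin empty voxel layers (default 2).
#' @return a [binary_volume()].
#' @export
make_bumpy_sphere <- function(radius, bump_amplitude, bump_frequency,
                              margin = 2) {
  if (radius < 1) stop("`radius` must be >= 1")
  if (bump_amplitude < 0) stop("`bump_amplitude` must be >= 0")
  g <- shape_grid(radius + bump_amplitude, margin)
  ax <- seq_len(g$side) - g$center
  n <- g$side
  x <- array(ax, dim = c(n, n, n))
  y <- aperm(x, c(2L, 1L, 3L))
  z <- aperm(x, c(3L, 2L, 1L))
  d <- sqrt(x^2 + y^2 + z^2)
  theta <- acos(ifelse(d > 0, z / pmax(d, .Machine$double.eps), 1))
  phi <- atan2(y, x)
  reff <- radius +
    bump_amplitude * sin(bump_frequency * theta) * sin(bump_frequency * phi)
  binary_volume(d <= reff)
}
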