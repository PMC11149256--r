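# Independent brute-force oracles used across the suite. These are
# deliberately written with different algorithms than the package code
# they check.

# --- morphology: shift-OR dilation / erosion on small padded grids ----

oracle_ball_offsets <- function(radius) {
  r <- as.integer(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, , drop = FALSE]
}

oracle_dilate <- function(grid, radius) {
  d <- dim(grid)
  r <- as.integer(radius)
  pd <- d + 2L * r
  a <- array(FALSE, pd)
  out <- array(FALSE, pd)
  a[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- grid
  off <- oracle_ball_offsets(radius)
  fg <- which(a, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    out[cbind(fg[, 1] + off$dx[k], fg[, 2] + off$dy[k], fg[, 3] + off$dz[k])] <- TRUE
  }
  out[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

oracle_close <- function(grid, radius) {
  d <- dim(grid)
  r <- as.integer(radius)
  pd <- d + 2L * r
  a <- array(FALSE, pd)
  a[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- grid
  dil <- oracle_dilate(a, radius)
  # erosion = complement of dilation of complement
  ero <- !oracle_dilate(!dil, radius)
  ero[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

# --- contours: even-odd rasterization of traced loops ----------------

# is point (px, py) strictly inside the closed polygon given by an
# n x 2 vertex matrix? (ray casting towards +x)
oracle_point_in_poly <- function(px, py, v) {
  n <- nrow(v)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- v[i, 2]; yj <- v[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- v[i, 1] + (py - yi) / (yj - yi) * (v[j, 1] - v[i, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# rebuild the mask from loops by even-odd filling at pixel centers
oracle_rasterize <- function(loops, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      px <- i - 0.5; py <- j - 0.5   # center of 0-based pixel (i-1, j-1)
      cnt <- 0L
      for (lp in loops)
        if (oracle_point_in_poly(px, py, lp$vertices)) cnt <- cnt + 1L
      m[i, j] <- (cnt %% 2L) == 1L
    }
  }
  m
}

# does the mask contain a saddle (checkerboard 2x2 window)? crack loops
# legitimately revisit the shared corner there
has_saddle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2 || nc < 2) return(FALSE)
  a <- m[-nr, -nc]; b <- m[-nr, -1]; c <- m[-1, -nc]; d <- m[-1, -1]
  any((a & d & !b & !c) | (!a & !d & b & c))
}

# --- DSS: exhaustive chord/distance run checker ----------------------

# perpendicular distance of point p to the infinite line through a, b,
# computed via the parallelogram area (independent of chord_dist's form)
oracle_line_dist <- function(p, a, b) {
  ab <- b - a
  ap <- p - a
  nrm <- sqrt(sum(ab^2))
  if (nrm == 0) return(sqrt(sum(ap^2)))
  abs(ab[1] * ap[2] - ab[2] * ap[1]) / nrm
}

oracle_run_ok <- function(v, i, j, width) {
  if (j - i < 2) return(TRUE)
  for (k in (i + 1):(j - 1))
    if (oracle_line_dist(v[k, ], v[i, ], v[j, ]) > width / 2) return(FALSE)
  TRUE
}

# --- rank-sum: exact enumeration of all group assignments ------------

# distribution of the Mann-Whitney U of "group b" over all
# choose(n1+n2, n2) assignments of the pooled values
oracle_u_distribution <- function(pooled, n2) {
  N <- length(pooled)
  r <- rank(pooled)
  combs <- utils::combn(N, n2)
  apply(combs, 2, function(idx) sum(r[idx]) - n2 * (n2 + 1) / 2)
}

# --- misc fixtures ---------------------------------------------------

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# random simple convex polygon: convex hull of random points, in CCW order
random_convex_polygon <- function(n = 12, scale = 10) {
  pts <- matrix(stats::rnorm(2 * max(n, 4), sd = scale), ncol = 2)
  h <- grDevices::chull(pts)          # clockwise order
  pts[rev(h), , drop = FALSE]         # counterclockwise
}
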