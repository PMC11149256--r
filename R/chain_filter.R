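#' Stair-stepping filter parameters
#'
#' Settings for the two-step contour filter: vertex downsampling by a
#' fixed stride, then a digital-straight-segment (DSS) polygonal
#' approximation that keeps only vertices starting maximal straight
#' runs.
#'
#' @param dsf positive integer downsampling factor (default 10); every
#'   `dsf`-th contour vertex is kept before DSS.
#' @param strip_width DSS tolerance in voxel units (default 1.0): a run
#'   of vertices counts as straight while every intermediate vertex lies
#'   within perpendicular distance `strip_width/2` of the run's chord.
#' @param min_vertices minimum vertices a closed filtered contour keeps
#'   (default 3); downsampling reduces its effective stride rather than
#'   collapse a small contour below this.
#' @param holes if `TRUE` (default) inner (hole) contours are filtered
#'   and contribute to tortuosity alongside outer contours.
#' @param auto_dsf if `TRUE`, [tortuosity_3d()] rescales `dsf` with the
#'   object size (`min bounding-box extent / 14`, at least 1): a fixed
#'   stride under-filters the stair-stepping artifact on very large
#'   objects. Off by default.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(dsf = 10, strip_width = 1.0, min_vertices = 3,
                          holes = TRUE, auto_dsf = FALSE) {
  dsf <- as.integer(dsf)
  if (dsf < 1L) stop("`dsf` must be >= 1")
  if (strip_width <= 0) stop("`strip_width` must be > 0")
  min_vertices <- as.integer(min_vertices)
  if (min_vertices < 1L) stop("`min_vertices` must be >= 1")
  structure(
    list(dsf = dsf, strip_width = strip_width,
         min_vertices = min_vertices, holes = isTRUE(holes),
         auto_dsf = isTRUE(auto_dsf)),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "<filter_params dsf=%d strip_width=%g min_vertices=%d holes=%s auto_dsf=%s>\n",
    x$dsf, x$strip_width, x$min_vertices, x$holes, x$auto_dsf))
  invisible(x)
}

as_polyline <- function(vertices, closed, source = NULL) {
  structure(list(vertices = vertices, closed = closed, source = source),
            class = "polyline")
}

#' Downsample a contour's vertices
#'
#' Keeps vertices at cyclic indices 0, dsf, 2*dsf, ... from the
#' contour's canonical (lexicographically smallest) start vertex. If
#' fewer than `min_vertices` vertices would survive, the effective
#' stride is reduced to `floor(N / min_vertices)` (at least 1) so small
#' contours keep a usable loop.
#'
#' @param contour a contour from [trace_contours()] (or a `polyline`).
#' @param params a [filter_params()].
#' @return a closed `polyline`.
#' @export
downsample_contour <- function(contour, params = filter_params()) {
  v <- contour$vertices
  closed <- if (inherits(contour, "polyline")) contour$closed else TRUE
  n <- nrow(v)
  dsf <- params$dsf
  if (ceiling(n / dsf) < params$min_vertices)
    dsf <- max(1L, n %/% params$min_vertices)
  keep <- seq.int(1L, n, by = dsf)
  as_polyline(v[keep, , drop = FALSE], closed, source = contour)
}

# max perpendicular distance of points (matrix) from the line through a, b;
# if a == b, plain Euclidean distance from a.
chord_dist <- function(pts, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2))
  abs((pts[, 1L] - a[1L]) * d[2L] - (pts[, 2L] - a[2L]) * d[1L]) / len
}

# does the run pts[i..j] (indices into pts) fit a strip of given width?
run_fits <- function(pts, i, j, width) {
  if (j - i < 2L) return(TRUE)
  mid <- (i + 1L):(j - 1L)
  all(chord_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ]) <= width / 2)
}

#' Digital-straight-segment simplification
#'
#' Greedy polygonal approximation in the spirit of the narrowest-strip
#' DSS criterion: starting from a vertex, a straight run is extended to
#' the farthest vertex such that every intermediate vertex lies within
#' perpendicular distance `strip_width/2` of the chord joining the run's
#' endpoints; the retained vertices are the run endpoints. Because the
#' input vertices are downsampled (no longer lattice-adjacent), the
#' classical arithmetic DSS recognition does not apply verbatim and the
#' strip criterion is evaluated with real-valued distances.
#'
#' For closed polylines the simplification starts at the vertex farthest
#' from the loop centroid (almost surely a true corner, so the cyclic
#' seam does not split a straight run), proceeds cyclically, and finally
#' merges the runs on either side of the start vertex if their union
#' still fits one strip.
#'
#' @param p a `polyline` (from [downsample_contour()], or built from an
#'   n x 2 vertex matrix).
#' @param params a [filter_params()].
#' @return a simplified `polyline` over a subset of `p`'s vertices;
#'   closed outputs keep at least `min_vertices` vertices, open outputs
#'   at least their two endpoints.
#' @export
dss_simplify <- function(p, params = filter_params()) {
  v <- p$vertices
  storage.mode(v) <- "double"
  # collapse consecutive duplicates (cyclically for closed polylines)
  n <- nrow(v)
  if (n > 1L) {
    nxt <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
    dup <- rowSums(abs(v - nxt)) == 0
    if (p$closed) keep <- !dup else keep <- c(!dup[-n], TRUE)
    v <- v[keep, , drop = FALSE]
    n <- nrow(v)
  }
  w <- params$strip_width

  if (!p$closed) {
    if (n <= 2L) return(as_polyline(v, FALSE, p$source))
    bp <- 1L
    i <- 1L
    while (i < n) {
      j <- i + 1L
      while (j < n && run_fits(v, i, j + 1L, w)) j <- j + 1L
      bp <- c(bp, j)
      i <- j
    }
    return(as_polyline(v[bp, , drop = FALSE], FALSE, p$source))
  }

  if (n <= params$min_vertices) return(as_polyline(v, TRUE, p$source))

  # start at the vertex farthest from the centroid
  ctr <- colMeans(v)
  s <- which.max((v[, 1L] - ctr[1L])^2 + (v[, 2L] - ctr[2L])^2)
  if (s > 1L) v <- v[c(s:n, seq_len(s - 1L)), , drop = FALSE]
  vv <- rbind(v, v[1L, , drop = FALSE])   # unwrap the cycle

  bp <- 1L
  i <- 1L
  while (i <= n) {
    j <- i + 1L
    while (j <= n && run_fits(vv, i, j + 1L, w)) j <- j + 1L
    if (j <= n) bp <- c(bp, j)
    i <- j
  }
  # seam merge: drop the start vertex if the runs before and after it
  # jointly fit one strip
  if (length(bp) > params$min_vertices) {
    last <- bp[length(bp)]
    b2 <- bp[2L]
    seam <- rbind(vv[last:(n + 1L), , drop = FALSE],
                  v[2L:b2, , drop = FALSE])
    if (nrow(seam) < 3L ||
        all(chord_dist(seam[2:(nrow(seam) - 1L), , drop = FALSE],
                       seam[1L, ], seam[nrow(seam), ]) <= w / 2))
      bp <- bp[-1L]
  }
  if (length(bp) < params$min_vertices) {
    # degenerate loop: fall back to evenly spaced vertices
    bp <- unique(round(seq(1L, n, length.out = params$min_vertices + 1L)))
    bp <- bp[bp <= n]
  }
  as_polyline(v[bp, , drop = FALSE], TRUE, p$source)
}

#' Filter the stair-stepping artifact from a contour
#'
#' Composition of the two filter steps in their normative order:
#' [downsample_contour()] first, then [dss_simplify()]. The result is
#' the straight-line-segment approximation of the slice contour from
#' which the Slope Chain Code is built.
#'
#' @param contour a contour from [trace_contours()].
#' @param params a [filter_params()].
#' @return a `polyline`.
#' @export
filter_contour <- function(contour, params = filter_params()) {
  dss_simplify(downsample_contour(contour, params), params)
}
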