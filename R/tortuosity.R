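#' 3D tortuosity of a voxelized object
#'
#' The core measure: for each of the three grid axes, every slice that
#' intersects the object is traced ([trace_contours()]), filtered
#' ([filter_contour()]) and encoded as a Slope Chain Code; the summed
#' absolute slope changes of each slice are averaged over that axis's
#' foreground-intersecting slice count, and the three axis means are
#' summed:
#' \deqn{\tau_{3D} = \frac{\sum_i \sum_n |x_{ni}|}{S_X}
#'              + \frac{\sum_j \sum_m |y_{mj}|}{S_Y}
#'              + \frac{\sum_k \sum_l |z_{lk}|}{S_Z}}
#' For a convex closed surface every slice contour is convex, each
#' contributes exactly 2, and \eqn{\tau_{3D} = 6}.
#'
#' `S_X`, `S_Y`, `S_Z` count only slices intersecting the object, never
#' empty padding slices; counting empty slices would make the measure
#' depend on the surrounding array size. Slices whose contours all
#' collapse below `min_vertices` still count in the denominator (they
#' intersect the object) but contribute 0.
#'
#' @param vol a [binary_volume()] with at least one foreground voxel;
#'   objects touching the array border are padded internally by one
#'   empty layer first.
#' @param params a [filter_params()]. With `auto_dsf = TRUE` the
#'   downsampling factor is rescaled to
#'   `max(1, round(min bounding-box extent / 14))`.
#' @return an object of class `tau3d_result`: list with `tau3d`,
#'   `axis_means` (named X/Y/Z), `S` (foreground slice counts),
#'   `per_axis_sums` (per-slice tortuosity vectors, named by slice
#'   index), `per_slice` (data frame: axis, index, n_contours, tau) and
#'   `params`.
#' @examples
#' tortuosity_3d(make_cube(11))$tau3d   # 6
#' @export
tortuosity_3d <- function(vol, params = filter_params()) {
  stopifnot(inherits(vol, "binary_volume"))
  if (foreground_count(vol) == 0L) stop("no object: empty foreground")

  g <- vol$grid
  d <- dim(g)
  touches <-
    any(g[1L, , ]) || any(g[d[1L], , ]) ||
    any(g[, 1L, ]) || any(g[, d[2L], ]) ||
    any(g[, , 1L]) || any(g[, , d[3L]])
  if (touches) {
    gp <- array(FALSE, dim = d + 2L)
    gp[1L + seq_len(d[1L]), 1L + seq_len(d[2L]), 1L + seq_len(d[3L])] <- g
    vol <- binary_volume(gp, spacing = vol$spacing)
  }

  if (params$auto_dsf) {
    fg <- which(vol$grid, arr.ind = TRUE)
    ext <- apply(fg, 2L, function(ix) diff(range(ix)) + 1L)
    params$dsf <- max(1L, as.integer(round(min(ext) / 14)))
  }

  per_axis <- list()
  per_slice <- list()
  for (axis in c("X", "Y", "Z")) {
    slices <- extract_slices(vol, axis)
    slices <- Filter(function(s) !s$empty, slices)
    taus <- numeric(length(slices))
    ncs <- integer(length(slices))
    for (i in seq_along(slices)) {
      cs <- trace_contours(slices[[i]])
      ncs[i] <- length(cs)
      taus[i] <- slice_tortuosity(cs, params)
    }
    names(taus) <- vapply(slices, function(s) s$index, integer(1))
    per_axis[[axis]] <- taus
    per_slice[[axis]] <- data.frame(
      axis = axis,
      index = as.integer(names(taus)),
      n_contours = ncs,
      tau = unname(taus)
    )
  }

  S <- vapply(per_axis, length, integer(1))
  if (any(S < 1L)) stop("no object: an axis has no foreground slices")
  axis_means <- vapply(per_axis, mean, numeric(1))
  structure(
    list(
      tau3d = sum(axis_means),
      axis_means = axis_means,
      S = S,
      per_axis_sums = per_axis,
      per_slice = do.call(rbind, per_slice),
      params = params
    ),
    class = "tau3d_result"
  )
}

#' @export
print.tau3d_result <- function(x, ...) {
  cat(sprintf("<tau3d_result tau3d = %.6g>\n", x$tau3d))
  cat(sprintf("  axis means: X %.6g (S=%d)  Y %.6g (S=%d)  Z %.6g (S=%d)\n",
              x$axis_means[["X"]], x$S[["X"]],
              x$axis_means[["Y"]], x$S[["Y"]],
              x$axis_means[["Z"]], x$S[["Z"]]))
  cat(sprintf("  params: dsf=%d strip_width=%g holes=%s\n",
              x$params$dsf, x$params$strip_width, x$params$holes))
  invisible(x)
}

#' Serialize a tortuosity result to JSON
#'
#' @param x a `tau3d_result`.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tau3d_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "tau3d_result"))
  obj <- list(
    tau3d = x$tau3d,
    axis_means = as.list(x$axis_means),
    S = as.list(x$S),
    params = list(
      dsf = x$params$dsf, strip_width = x$params$strip_width,
      min_vertices = x$params$min_vertices, holes = x$params$holes,
      auto_dsf = x$params$auto_dsf
    ),
    per_slice = `rownames<-`(x$per_slice, NULL)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 6)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Sphere validation sweep
#'
#' Measures the absolute error \eqn{\Delta x = |\tau_{3D} - 6|} of the
#' full pipeline on voxelized spheres (convex closed surfaces, true
#' value 6) across radii and generation angles. Deterministic: the
#' generators use no randomness.
#'
#' @param radii numeric vector of sphere radii (voxels).
#' @param angles numeric vector of generation angles in degrees.
#' @param params a [filter_params()].
#' @return an object of class `validation_grid`: list with `radii`,
#'   `angles`, `delta` (radii x angles matrix of absolute errors) and
#'   `tau` (the raw tau3d values).
#' @export
validate_spheres <- function(radii = seq(10, 70, by = 10),
                             angles = seq(0, 315, by = 45),
                             params = filter_params()) {
  delta <- matrix(NA_real_, length(radii), length(angles),
                  dimnames = list(radius = radii, angle = angles))
  tau <- delta
  for (i in seq_along(radii)) {
    for (j in seq_along(angles)) {
      res <- tortuosity_3d(make_sphere(radii[i], angle = angles[j]), params)
      tau[i, j] <- res$tau3d
      delta[i, j] <- abs(res$tau3d - 6)
    }
  }
  structure(list(radii = radii, angles = angles, delta = delta, tau = tau),
            class = "validation_grid")
}

#' @export
print.validation_grid <- function(x, ...) {
  cat(sprintf(
    "<validation_grid %d radii x %d angles, max |tau3d - 6| = %.4g>\n",
    length(x$radii), length(x$angles), max(x$delta)))
  invisible(x)
}

#' Tortuosity under progressive morphological smoothing
#'
#' Applies [morphological_closing()] with each listed ball radius and
#' measures tau3d, prepended with the unsmoothed (radius 0) value.
#' Closing fills concavities, so for a rough, folded surface the
#' sequence is expected to decrease as the structuring element grows.
#'
#' @param vol a [binary_volume()].
#' @param radii integer vector of structuring-element radii (may be
#'   empty, leaving only the unsmoothed entry).
#' @param params a [filter_params()].
#' @return data frame with columns `radius` and `tau3d`, one row for
#'   radius 0 plus one per requested radius, in order.
#' @export
closing_experiment <- function(vol, radii = c(2, 4, 6, 8),
                               params = filter_params()) {
  radii <- as.integer(radii)
  taus <- numeric(length(radii) + 1L)
  taus[1L] <- tortuosity_3d(vol, params)$tau3d
  for (i in seq_along(radii))
    taus[i + 1L] <- tortuosity_3d(morphological_closing(vol, radii[i]),
                                  params)$tau3d
  data.frame(radius = c(0L, radii), tau3d = taus)
}
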