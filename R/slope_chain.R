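#' Slope Chain Code of a polyline
#'
#' Encodes a polyline as the sequence of slope changes between
#' contiguous straight-line segments: at each vertex the signed turning
#' angle between the incoming and outgoing segment directions, divided
#' by pi, giving elements in the open interval (-1, 1). Positive turns
#' are counterclockwise (2D cross-product convention). A closed polyline
#' with n vertices yields n elements (one turn per vertex, cyclically);
#' an open one yields n - 2 (interior vertices only).
#'
#' An exact reversal (turning angle of +-pi, so |a| = 1) falls outside
#' the open interval; it is resolved by deleting the apex vertex and
#' recomputing, which keeps the chain honestly inside (-1, 1) rather
#' than clamping.
#'
#' @param p a `polyline`, or an n x 2 vertex matrix (taken as closed
#'   when `closed = TRUE`).
#' @param closed used only when `p` is a bare matrix.
#' @return an object of class `slope_chain`: list with `elements`
#'   (numeric vector, each in (-1, 1)) and `closed`.
#' @examples
#' slope_changes(rbind(c(0, 0), c(1, 0), c(1, 1)), closed = FALSE)
#' @export
slope_changes <- function(p, closed = TRUE) {
  if (is.matrix(p)) p <- as_polyline(p, closed)
  v <- p$vertices
  storage.mode(v) <- "double"
  closed <- p$closed
  repeat {
    n <- nrow(v)
    if (n < 3L)
      stop("chain undefined: polyline has fewer than 2 segments")
    if (closed) {
      vin <- v - v[c(n, seq_len(n - 1L)), , drop = FALSE]
      vout <- v[c(2:n, 1L), , drop = FALSE] - v
    } else {
      idx <- 2:(n - 1L)
      vin <- v[idx, , drop = FALSE] - v[idx - 1L, , drop = FALSE]
      vout <- v[idx + 1L, , drop = FALSE] - v[idx, , drop = FALSE]
    }
    cr <- vin[, 1L] * vout[, 2L] - vin[, 2L] * vout[, 1L]
    dt <- vin[, 1L] * vout[, 1L] + vin[, 2L] * vout[, 2L]
    a <- atan2(cr, dt) / pi
    rev_tol <- 1e-12
    bad <- which(abs(a) >= 1 - rev_tol)
    if (length(bad) == 0L)
      return(structure(list(elements = a, closed = closed),
                       class = "slope_chain"))
    # delete apex vertices of exact reversals and recompute
    apex <- if (closed) bad else bad + 1L
    v <- v[-apex, , drop = FALSE]
  }
}

#' @export
print.slope_chain <- function(x, ...) {
  cat(sprintf("<slope_chain %s, %d element(s), tau = %.6g>\n",
              if (x$closed) "closed" else "open",
              length(x$elements), tortuosity_2d(x)))
  invisible(x)
}

#' 2D tortuosity of a slope chain
#'
#' The sum of the absolute values of the chain elements. For a simple
#' convex closed polygon the total absolute turning is exactly 2 pi, so
#' the tortuosity is exactly 2 whatever the vertex count; deviations
#' above 2 measure concavity and wiggliness.
#'
#' @param chain a `slope_chain` (or a `polyline`/matrix, which is first
#'   encoded with [slope_changes()]).
#' @return nonnegative real.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' tortuosity_2d(slope_changes(sq))   # 2
#' @export
tortuosity_2d <- function(chain) {
  if (!inherits(chain, "slope_chain")) chain <- slope_changes(chain)
  sum(abs(chain$elements))
}

#' Total tortuosity of one slice
#'
#' Runs every contour of a slice through the stair-stepping filter and
#' the Slope Chain Code, and sums the per-contour tortuosities. Hole
#' contours are included unless `params$holes` is `FALSE`.
#'
#' A contour that collapses below 3 distinct vertices after filtering
#' (possible for degenerate pinched loops) has no usable polygon and
#' contributes 0.
#'
#' @param contours list of contours from [trace_contours()].
#' @param params a [filter_params()].
#' @return nonnegative real; 0 for an empty slice.
#' @export
slice_tortuosity <- function(contours, params = filter_params()) {
  if (length(contours) == 0L) return(0)
  if (!params$holes) contours <- Filter(function(c) c$is_outer, contours)
  if (length(contours) == 0L) return(0)
  tau_one <- function(cc) {
    pl <- filter_contour(cc, params)
    if (nrow(pl$vertices) < 3L) return(0)
    ch <- tryCatch(slope_changes(pl), error = function(e) NULL)
    if (is.null(ch)) 0 else tortuosity_2d(ch)
  }
  sum(vapply(contours, tau_one, numeric(1)))
}
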