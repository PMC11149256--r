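#' Trace crack-boundary contours of a binary slice
#'
#' Traces the complete boundary of every connected foreground region of
#' a 2D mask as closed loops on the inter-pixel "crack" lattice: the
#' pixel at 0-based index (x, y) occupies the unit square
#' \eqn{[x,x+1)\times[y,y+1)}, and contour vertices are the integer
#' pixel corners. Consecutive vertices differ by one unit step, so the
#' stair-stepping structure of the digitized boundary (unit steps, 90
#' degree turns) is explicit in the output and is removed later by
#' [filter_contour()].
#'
#' Foreground is 8-connected and background 4-connected (the standard
#' Jordan-consistent pairing): where two foreground pixels meet only
#' diagonally the walker pinches through the shared corner and keeps the
#' component's boundary as a single loop. Outer boundaries are oriented
#' counterclockwise (positive signed area), hole boundaries clockwise;
#' each loop starts at its lexicographically smallest vertex.
#'
#' @param slice a slice plane from [extract_slices()], or a logical
#'   matrix.
#' @return list of contours; each is a list with `vertices` (n x 2
#'   integer matrix of 0-based corner coordinates, first vertex not
#'   repeated at the end), `axis`, `slice_index`, `is_outer` and
#'   `area` (signed, in pixels).
#' @export
trace_contours <- function(slice) {
  if (is.matrix(slice)) slice <- list(axis = NA, index = NA_integer_,
                                      mask = slice, empty = !any(slice))
  m <- slice$mask
  if (!is.logical(m)) m <- m != 0
  if (!any(m)) return(list())
  nr <- nrow(m); nc <- ncol(m)
  nvx <- nr + 1L; nvy <- nc + 1L   # vertex lattice extents

  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2L:(nr + 1L), 2L:(nc + 1L)] <- m
  core <- pad[2L:(nr + 1L), 2L:(nc + 1L), drop = FALSE]

  # Directed boundary cracks, foreground kept on the left of travel:
  # bottom edges run +y', i.e. in (x,y): bottom +x, top -x, left -y,
  # right +y.  Pixel (i,j) is 1-based here; its corners are the 0-based
  # vertices (i-1..i, j-1..j).  Vertex (vx,vy) has id vx*nvy + vy + 1.
  vid <- function(vx, vy) vx * nvy + vy + 1L

  e_from <- integer(0); e_to <- integer(0); e_dir <- integer(0)
  add <- function(w, f_vx, f_vy, t_vx, t_vy, dir) {
    if (length(w) == 0L) return()
    i <- ((w - 1L) %% nr) + 1L
    j <- ((w - 1L) %/% nr) + 1L
    e_from <<- c(e_from, vid(i - 1L + f_vx, j - 1L + f_vy))
    e_to   <<- c(e_to,   vid(i - 1L + t_vx, j - 1L + t_vy))
    e_dir  <<- c(e_dir, rep.int(dir, length(w)))
  }
  # dir codes: 1 = +x, 2 = -x, 3 = -y, 4 = +y
  add(which(core & !pad[2:(nr + 1), 1:nc]),       0L, 0L, 1L, 0L, 1L) # bottom
  add(which(core & !pad[2:(nr + 1), 3:(nc + 2)]), 1L, 1L, 0L, 1L, 2L) # top
  add(which(core & !pad[1:nr, 2:(nc + 1)]),       0L, 1L, 0L, 0L, 3L) # left
  add(which(core & !pad[3:(nr + 2), 2:(nc + 1)]), 1L, 0L, 1L, 1L, 4L) # right

  ne <- length(e_from)
  # per-vertex outgoing edges (at most two: only at saddle corners)
  out1 <- integer(nvx * nvy); out2 <- integer(nvx * nvy)
  out1[e_from] <- seq_len(ne)
  dups <- which(duplicated(e_from))
  if (length(dups)) out2[e_from[dups]] <- match(e_from[dups], e_from)

  # successor preference at a saddle: take the right (clockwise) turn,
  # which realizes 8-connected foreground / 4-connected background.
  # right turn of dir: +x->-y, -y->-x, -x->+y, +y->+x
  rturn <- c(3L, 4L, 2L, 1L)

  used <- logical(ne)
  order_by_start <- order(e_from, e_dir)
  loops <- vector("list", 8L)
  nl <- 0L

  for (e0 in order_by_start) {
    if (used[e0]) next
    verts <- integer(256L); nv <- 0L
    e <- e0
    repeat {
      used[e] <- TRUE
      nv <- nv + 1L
      if (nv > length(verts)) verts <- c(verts, integer(length(verts)))
      verts[nv] <- e_from[e]
      v <- e_to[e]
      c1 <- out1[v]; c2 <- out2[v]
      if (c2 == 0L) {
        nxt <- c1
      } else {
        # two candidates: prefer the right turn w.r.t. incoming direction
        want <- rturn[e_dir[e]]
        nxt <- if (e_dir[c1] == want) c1 else c2
      }
      if (nxt == e0) break
      e <- nxt
    }
    verts <- verts[seq_len(nv)]
    vx <- (verts - 1L) %/% nvy
    vy <- (verts - 1L) %% nvy
    # canonical start: lexicographically smallest (x, then y) vertex
    s <- which.min(vx * (nvy + 1L) + vy)
    if (s > 1L) {
      rot <- c(s:nv, seq_len(s - 1L))
      vx <- vx[rot]; vy <- vy[rot]
    }
    area <- sum(vx * c(vy[-1L], vy[1L]) - c(vx[-1L], vx[1L]) * vy) / 2
    nl <- nl + 1L
    if (nl > length(loops)) loops <- c(loops, vector("list", length(loops)))
    loops[[nl]] <- list(
      vertices = cbind(x = vx, y = vy),
      axis = slice$axis, slice_index = slice$index,
      is_outer = area > 0, area = area
    )
  }
  loops[seq_len(nl)]
}

#' Crack-path length of a contour
#'
#' Every step of a crack contour is one unit long, so the perimeter in
#' unit steps equals the vertex count.
#'
#' @param contour a contour from [trace_contours()].
#' @return nonnegative integer.
#' @export
contour_perimeter <- function(contour) {
  nrow(contour$vertices)
}
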