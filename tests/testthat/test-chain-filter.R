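test_that("downsampling keeps every dsf-th vertex with the small-contour fallback", {
  # 200-vertex loop: a digitized circle-ish polygon is unnecessary, any
  # 200-vertex contour works for index arithmetic
  m <- matrix(FALSE, 60, 60)
  m[10:50, 10:50] <- TRUE
  cs <- trace_contours(m)          # 164-vertex square loop
  p <- downsample_contour(cs[[1]], filter_params(dsf = 10))
  expect_equal(nrow(p$vertices), 17L)   # ceiling(164/10)
  expect_equal(p$vertices, cs[[1]]$vertices[seq(1, 164, by = 10), ])
  expect_true(p$closed)

  blk <- trace_contours({m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE; m})[[1]]
  p8 <- downsample_contour(blk, filter_params(dsf = 10, min_vertices = 3))
  expect_equal(nrow(p8$vertices), 4L)   # effective factor floor(8/3) = 2
  expect_equal(p8$vertices, blk$vertices[c(1, 3, 5, 7), ])

  px <- trace_contours({m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE; m})[[1]]
  p4 <- downsample_contour(px, filter_params(dsf = 10))
  expect_equal(nrow(p4$vertices), 4L)   # all kept
})

test_that("collinear open runs simplify to their endpoints", {
  p <- structure(list(vertices = rbind(c(0, 0), c(3, 0), c(5, 0), c(9, 0)),
                      closed = FALSE, source = NULL), class = "polyline")
  s <- dss_simplify(p, filter_params())
  expect_equal(s$vertices, rbind(c(0, 0), c(9, 0)))
})

test_that("a square loop with edge midpoints keeps exactly its corners", {
  v <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1),
             c(2, 2), c(1, 2), c(0, 2), c(0, 1))
  p <- structure(list(vertices = v, closed = TRUE, source = NULL),
                 class = "polyline")
  s <- dss_simplify(p, filter_params(strip_width = 1.0))
  got <- s$vertices[order(s$vertices[, 1], s$vertices[, 2]), ]
  expect_equal(got, rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2)))
})

test_that("stair-step simplification matches the brute-force chord criterion", {
  v <- rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2), c(3, 2))
  p <- structure(list(vertices = v, closed = FALSE, source = NULL),
                 class = "polyline")
  s <- dss_simplify(p, filter_params(strip_width = 1.0))
  # independent greedy oracle over exhaustive chord/distance checks
  bp <- 1L; i <- 1L; n <- nrow(v)
  while (i < n) {
    j <- i + 1L
    while (j < n && oracle_run_ok(v, i, j + 1L, 1.0)) j <- j + 1L
    bp <- c(bp, j); i <- j
  }
  expect_equal(s$vertices, v[bp, , drop = FALSE])
  # under the chord criterion the 45-degree stair does NOT collapse to
  # its endpoints: the mid-step corners sit 0.55 > 0.5 off the full chord
  expect_gt(nrow(s$vertices), 2L)
})

test_that("retained runs are maximal under the exhaustive strip oracle", {
  set.seed(5)
  polys <- list()
  for (rep in 1:12) {
    n <- sample(5:30, 1)
    t <- sort(stats::runif(n, 0, 2 * pi * 0.8))
    v <- cbind(10 * cos(t) + stats::rnorm(n, sd = 0.2),
               10 * sin(t) + stats::rnorm(n, sd = 0.2))
    polys[[rep]] <- v
  }
  polys[[13]] <- cbind(0:20, rep(0, 21))                 # exactly straight
  polys[[14]] <- cbind(0:10, c(0, 0.3, 0, -0.3) [1 + (0:10) %% 4])
  for (v in polys) {
    p <- structure(list(vertices = v, closed = FALSE, source = NULL),
                   class = "polyline")
    s <- dss_simplify(p, filter_params(strip_width = 1.0))
    key <- function(m) paste(m[, 1], m[, 2])
    idx <- match(key(s$vertices), key(v))
    expect_false(anyNA(idx))
    expect_equal(idx[1], 1L)
    expect_equal(idx[length(idx)], nrow(v))
    for (k in seq_len(length(idx) - 1L)) {
      expect_true(oracle_run_ok(v, idx[k], idx[k + 1L], 1.0))
      if (idx[k + 1L] < nrow(v))   # maximality: one-longer run must fail
        expect_false(oracle_run_ok(v, idx[k], idx[k + 1L] + 1L, 1.0))
    }
  }
})

test_that("simplification only ever drops vertices (monotone subsets)", {
  m <- matrix(FALSE, 40, 40)
  m[8:32, 8:32] <- TRUE; m[15:25, 15:25] <- FALSE
  for (cc in trace_contours(m)) {
    ds <- downsample_contour(cc, filter_params())
    ss <- dss_simplify(ds, filter_params())
    key <- function(v) paste(v[, 1], v[, 2])
    expect_true(all(key(ds$vertices) %in% key(cc$vertices)))
    expect_true(all(key(ss$vertices) %in% key(ds$vertices)))
  }
})

test_that("a vanishing strip width is the identity without collinear triples", {
  set.seed(3)
  t <- sort(stats::runif(15, 0, 2 * pi))
  v <- cbind(cos(t) * (5 + stats::runif(15)), sin(t) * (5 + stats::runif(15)))
  p <- structure(list(vertices = v, closed = TRUE, source = NULL),
                 class = "polyline")
  s <- dss_simplify(p, filter_params(strip_width = 1e-12))
  expect_equal(nrow(s$vertices), 15L)
})

test_that("filtering a digitized disk yields a convex polygon with tau 2", {
  m <- matrix(FALSE, 70, 70)
  ctr <- 35.5
  for (i in 1:70) for (j in 1:70)
    m[i, j] <- (i - ctr)^2 + (j - ctr)^2 <= 30^2
  cc <- trace_contours(m)[[1]]
  pl <- filter_contour(cc, filter_params())
  v <- pl$vertices
  n <- nrow(v)
  nxt <- v[c(2:n, 1), ] - v
  cr <- nxt[, 1] * nxt[c(2:n, 1), 2] - nxt[, 2] * nxt[c(2:n, 1), 1]
  expect_true(all(cr > 0) || all(cr < 0))   # convex
  tau <- tortuosity_2d(slope_changes(pl))
  expect_equal(tau, 2, tolerance = 0.33 / 2)
})

test_that("tiny contours keep at least min_vertices after filtering", {
  px <- trace_contours({m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE; m})[[1]]
  pl <- filter_contour(px, filter_params())
  expect_gte(nrow(pl$vertices), 3L)
  expect_true(pl$closed)
})
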