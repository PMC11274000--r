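# Geometric primitives against independent oracles and closed forms.

test_that("convex_hull keeps exactly the extreme points", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(2, 2))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4)
  expect_true(all(apply(h, 1, function(p) any(p[1] == c(0, 4)) || any(p[2] == c(0, 4)))))

  # all points on a circle are hull vertices
  circ <- circle_contour(24, 10, 20, 20)
  expect_equal(nrow(convex_hull(circ)), 24)

  # random interior points of a triangle vanish
  tri <- rbind(c(0, 0), c(40, 0), c(20, 30))
  set.seed(2)
  w <- matrix(rexp(3 * 100), ncol = 3); w <- w / rowSums(w)
  inner <- w %*% tri
  h2 <- convex_hull(rbind(tri, inner))
  expect_equal(nrow(h2), 3)
  expect_true(all(h2[, 1] %in% tri[, 1] & h2[, 2] %in% tri[, 2]))

  # hull is a subset of the input and contains every input point
  set.seed(3)
  pts <- cbind(runif(50, 0, 20), runif(50, 0, 20))
  h3 <- convex_hull(pts)
  expect_true(all(apply(h3, 1, function(p) any(pts[, 1] == p[1] & pts[, 2] == p[2]))))
  n3 <- nrow(h3)
  for (i in seq_len(nrow(pts))) {
    inside <- point_in_poly(pts[i, 1], pts[i, 2], h3)
    on_vertex <- any(abs(h3[, 1] - pts[i, 1]) < 1e-9 & abs(h3[, 2] - pts[i, 2]) < 1e-9)
    on_edge <- any(vapply(seq_len(n3), function(j) {
      a <- h3[j, ]; b <- h3[j %% n3 + 1, ]
      d <- point_line_distance(pts[i, ], a, b)
      d < 1e-9 && pts[i, 1] >= min(a[1], b[1]) - 1e-9 && pts[i, 1] <= max(a[1], b[1]) + 1e-9
    }, logical(1)))
    expect_true(inside || on_vertex || on_edge)
  }

  expect_error(convex_hull(cbind(0:5, 0:5)), class = "degenerate_geometry_error")
})

test_that("min_area_rect recovers constructed rectangles and their angles", {
  rect <- rbind(c(0, 0), c(30, 0), c(30, 10), c(0, 10))
  mr <- min_area_rect(rect)
  expect_equal(mr$long_side, 30)
  expect_equal(mr$short_side, 10)
  expect_equal(mr$angle_deg, 0)

  for (ang in c(15, -25, 40)) {
    mr2 <- min_area_rect(rotate_pts(rect, ang))
    expect_lt(abs(mr2$angle_deg - ang), 0.5)
    expect_lt(abs(mr2$long_side - 30), 1e-6)
  }

  # unit square: orientations 0 and 90 tie; smallest |angle| wins
  expect_equal(min_area_rect(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))$angle_deg, 0)

  expect_error(min_area_rect(cbind(1:4, 1:4)), class = "degenerate_geometry_error")
})

test_that("min_area_rect area never exceeds the bounding-rect area", {
  set.seed(7)
  for (k in 1:25) {
    pts <- cbind(runif(15, 0, 60), runif(15, 0, 40))
    mr <- min_area_rect(pts)
    br <- bounding_rect(pts)
    # compare on the same footing: tight continuous extents
    bw <- max(pts[, 1]) - min(pts[, 1]); bh <- max(pts[, 2]) - min(pts[, 2])
    expect_lte(mr$long_side * mr$short_side, bw * bh + 1e-9)
    expect_equal(unname(br[c("x1", "y1")] - br[c("x0", "y0")]), c(bw, bh) + 1)
  }
})

test_that("bounding_rect gives half-open pixel bounds", {
  expect_equal(unname(unclass(bounding_rect(rbind(c(2, 3), c(9, 7))))), c(2, 3, 10, 8))
  expect_equal(unname(unclass(bounding_rect(rbind(c(5, 5))))), c(5, 5, 6, 6))
  set.seed(8)
  pts <- matrix(sample(0:40, 100, TRUE), ncol = 2)
  br <- bounding_rect(pts)
  expect_equal(unname(unclass(br)),
               c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]) + 1, max(pts[, 2]) + 1))
  expect_error(bounding_rect(matrix(numeric(0), 0, 2)), class = "validation_error")
})

test_that("max_inscribed_rect equals exhaustive search on random masks", {
  m <- solid_mask(10, 8)
  r <- max_inscribed_rect(m)
  expect_equal(as.numeric(r), c(0, 0, 10, 8))
  expect_equal(attr(r, "area"), 80)

  # L-shape
  g <- matrix(FALSE, 14, 14)
  g[1:4, 1:10] <- TRUE; g[1:10, 1:4] <- TRUE
  expect_equal(as.numeric(max_inscribed_rect(binary_mask(g))), brute_max_rect(g)[1:4])

  g1 <- matrix(FALSE, 6, 6); g1[3, 4] <- TRUE
  expect_equal(as.numeric(max_inscribed_rect(binary_mask(g1))), c(3, 2, 4, 3))

  set.seed(42)
  for (k in 1:60) {
    h <- sample(2:12, 1); w <- sample(2:12, 1)
    g <- matrix(runif(h * w) < 0.6, h, w)
    if (!any(g)) next
    r <- max_inscribed_rect(binary_mask(g))
    expect_equal(unname(c(unclass(r), attr(r, "area"))), brute_max_rect(g))
  }

  expect_error(max_inscribed_rect(binary_mask(matrix(FALSE, 2, 2))),
               class = "empty_mask_error")
})

test_that("u_chord_curvature matches the circle closed form and sign rules", {
  circ <- circle_contour(360, 50, 100, 100)
  cs <- u_chord_curvature(circ, 90, 10)
  closed <- sqrt(1 - (50 * sin(2 * asin(10 / (2 * 50))) / 10)^2)
  expect_lt(abs(abs(cs$c) - closed), 1e-3)
  expect_lte(abs(cs$c), 1)
  expect_equal(sqrt(sum((cs$p_ib - cs$p_if)^2)), cs$D)

  # straight runs have zero curvature
  line <- cbind(seq(0, 18, by = 2), rep(3, 10))
  expect_equal(u_chord_curvature(line, 5, 4)$c, 0)
  expect_equal(u_chord_curvature(line, 5, 4)$s, 0)

  # mirror reflection negates the sign, preserves magnitude
  circm <- cbind(-circ[, 1], circ[, 2])
  expect_equal(u_chord_curvature(circm, 90, 10)$c, -cs$c, tolerance = 1e-9)

  expect_error(u_chord_curvature(circ[1:4, ], 2, 5), class = "validation_error")
  expect_error(u_chord_curvature(circ, 10, 0), class = "validation_error")
})

test_that("u_chord_curvature is invariant under rotation and translation", {
  circ <- circle_contour(360, 50, 100, 100)
  base <- abs(u_chord_curvature(circ, 45, 10)$c)
  for (ang in c(90, 180, 270)) {
    rc <- rotate_pts(circ, ang, c(100, 100))
    expect_lt(abs(abs(u_chord_curvature(rc, 45, 10)$c) - base), 1e-6)
  }
  shifted <- sweep(circ, 2, c(31.7, -12.2), `+`)
  expect_lt(abs(abs(u_chord_curvature(shifted, 45, 10)$c) - base), 1e-9)
  rc2 <- rotate_pts(circ, 33.3, c(100, 100))
  expect_lt(abs(abs(u_chord_curvature(rc2, 45, 10)$c) - base), 0.02)
})

test_that("point_line_distance matches the cross-product formula", {
  expect_equal(point_line_distance(c(0, 5), c(-1, 0), c(1, 0)), 5)
  expect_equal(point_line_distance(c(3, 3), c(0, 0), c(6, 6)), 0)
  set.seed(10)
  for (k in 1:20) {
    p <- runif(2, -10, 10); a <- runif(2, -10, 10); b <- runif(2, -10, 10)
    ref <- abs((b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])) /
      sqrt(sum((b - a)^2))
    expect_equal(point_line_distance(p, a, b), ref)
  }
  expect_error(point_line_distance(c(1, 1), c(2, 2), c(2, 2)), class = "validation_error")
})
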