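# Mask reading, rasterization, component handling and contour tracing.

test_that("load_mask thresholds gray levels and preserves dimensions", {
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 48, 64), tmp)
  m <- load_mask(tmp)
  expect_equal(dim(m), c(48L, 64L))
  expect_equal(mask_area(m), 48 * 64)

  png::writePNG(matrix(0, 48, 64), tmp)
  expect_equal(mask_area(load_mask(tmp)), 0)

  # checkerboard: pixel true iff (row + col) even, matches a parity oracle
  cb <- outer(0:7, 0:7, function(r, c) (r + c) %% 2 == 0) * 1
  png::writePNG(cb, tmp)
  m <- load_mask(tmp)
  expect_equal(mask_area(m), 32)
  for (p in list(c(0, 0), c(1, 0), c(3, 5), c(7, 7))) {
    expect_identical(m[p[2] + 1, p[1] + 1], (p[1] + p[2]) %% 2 == 0)
  }

  expect_error(load_mask(tmp, threshold = 0), class = "validation_error")
  expect_error(load_mask(file.path(tempdir(), "no-such.png")), class = "io_error")
})

test_that("load_mask foreground count is non-increasing in the threshold", {
  tmp <- withr::local_tempfile(fileext = ".png")
  set.seed(4)
  png::writePNG(matrix(runif(30 * 20), 20, 30), tmp)
  counts <- vapply(c(1, 50, 128, 200, 255),
                   function(t) mask_area(load_mask(tmp, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rasterize_polygons applies the center-inclusion even-odd rule", {
  sq <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  m <- rasterize_polygons(list(sq), 32, 32)
  expect_equal(mask_area(m), 100)
  # against the scalar point-in-polygon oracle over every pixel
  for (xx in 8:22) for (yy in 8:22) {
    expect_identical(m[yy + 1, xx + 1], point_in_poly(xx + 0.5, yy + 0.5, sq))
  }

  expect_equal(mask_area(rasterize_polygons(list(), 16, 16)), 0)

  # disjoint squares union additively
  sq2 <- sq + 15
  both <- rasterize_polygons(list(sq, sq2), 64, 64)
  expect_equal(mask_area(both),
               mask_area(rasterize_polygons(list(sq), 64, 64)) +
                 mask_area(rasterize_polygons(list(sq2), 64, 64)))

  expect_error(rasterize_polygons(list(rbind(c(1, 1), c(1, 1), c(2, 2))), 8, 8),
               class = "validation_error")
})

test_that("polygon annotation files round-trip through rasterization", {
  tmp <- withr::local_tempfile(fileext = ".json")
  ann <- list(imageWidth = 40, imageHeight = 30,
              shapes = list(list(label = "sheep",
                                 points = list(c(5, 5), c(25, 5), c(25, 15), c(5, 15)))))
  jsonlite::write_json(ann, tmp, auto_unbox = TRUE)
  rec <- read_polygon_annotation(tmp)
  m <- rasterize_polygons(rec$polygons, rec$width, rec$height)
  expect_equal(dim(m), c(30L, 40L))
  expect_equal(mask_area(m), 200)
})

test_that("largest_component keeps the biggest blob with a row-major tie-break", {
  g <- matrix(FALSE, 12, 12)
  g[2:6, 2:11] <- TRUE        # 50 px
  g[9:10, 2:11] <- TRUE       # 20 px
  out <- largest_component(binary_mask(g))
  expect_equal(mask_area(out), 50)
  expect_true(all(which(out, arr.ind = TRUE)[, 1] <= 6))

  # idempotence, never grows
  again <- largest_component(out)
  expect_identical(as.logical(again), as.logical(out))

  # equal-size blobs: the one containing the first row-major pixel wins
  g2 <- matrix(FALSE, 8, 8)
  g2[1:2, 1:5] <- TRUE   # 10 px starting at (0, 0)
  g2[6:7, 3:7] <- TRUE   # 10 px
  out2 <- largest_component(binary_mask(g2))
  expect_true(out2[1, 1])
  expect_equal(mask_area(out2), 10)

  expect_error(largest_component(binary_mask(matrix(FALSE, 3, 3))),
               class = "empty_mask_error")
})

test_that("components are 8-connected", {
  g <- matrix(FALSE, 4, 4); g[1, 1] <- TRUE; g[2, 2] <- TRUE; g[3, 3] <- TRUE
  expect_equal(n_components(binary_mask(g)), 1L)
  g[1, 4] <- TRUE
  expect_equal(n_components(binary_mask(g)), 2L)
})

test_that("extract_contour traces boundaries clockwise from the top-left", {
  ct <- extract_contour(solid_mask(5, 5))
  expect_equal(nrow(ct), 16)                   # perimeter pixels of a 5x5 square
  expect_equal(as.numeric(ct[1, ]), c(0, 0))   # top-left-most start
  # all points are boundary pixels: some 4-neighbor is outside the mask
  g <- matrix(TRUE, 5, 5)
  for (i in seq_len(nrow(ct))) {
    x <- ct[i, 1]; y <- ct[i, 2]
    nb <- rbind(c(x + 1, y), c(x - 1, y), c(x, y + 1), c(x, y - 1))
    outside <- apply(nb, 1, function(p)
      p[1] < 0 || p[1] > 4 || p[2] < 0 || p[2] > 4 || !g[p[2] + 1, p[1] + 1])
    expect_true(any(outside))
  }
  # clockwise with y down: the signed area of the traversal is negative in
  # the mathematical (y-up) sense, positive in image coordinates
  xs <- ct[, 1]; ys <- ct[, 2]
  a2 <- sum(xs * ys[c(2:16, 1)] - xs[c(2:16, 1)] * ys)
  expect_gt(a2, 0)

  bar <- extract_contour(binary_mask(matrix(TRUE, 1, 3)))
  expect_equal(nrow(unique(bar)), 3)
  expect_true(all(bar[, 2] == 0))
  # no two consecutive points identical
  expect_false(any(rowSums(abs(diff(bar))) == 0))

  expect_error(extract_contour(solid_mask(1, 1, frame = c(4, 4))),
               class = "validation_error")
  g2 <- matrix(FALSE, 6, 6); g2[1, 1] <- TRUE; g2[5, 5] <- TRUE
  expect_error(extract_contour(binary_mask(g2)), class = "validation_error")
  expect_error(extract_contour(binary_mask(matrix(FALSE, 3, 3))),
               class = "empty_mask_error")
})

test_that("rasterize/contour round trip stays near the polygon boundary", {
  # center-inclusion rasterization can leave an obtuse vertex up to ~1.4 px
  # from the nearest covered pixel center, so the bound is 1.5 px
  set.seed(9)
  for (k in 1:10) {
    nv <- sample(7:11, 1)
    ang <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)] + runif(nv, -0.12, 0.12)
    rad <- runif(nv, 9, 13)
    poly <- cbind(24 + rad * cos(ang), 16 + rad * sin(ang))
    poly <- poly[grDevices::chull(poly), , drop = FALSE]
    m <- rasterize_polygons(list(poly), 48, 32)
    if (!any(m)) next
    ct <- extract_contour(largest_component(m))
    # polygon boundary sampled densely
    n <- nrow(poly)
    bnd <- do.call(rbind, lapply(seq_len(n), function(i) {
      a <- poly[i, ]; b <- poly[i %% n + 1, ]
      t <- seq(0, 1, length.out = 50)
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    }))
    # contour pixel centers vs polygon boundary, both directions
    ctc <- ct + 0.5
    d1 <- max(apply(ctc, 1, function(p) min(sqrt((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2))))
    d2 <- max(apply(bnd, 1, function(p) min(sqrt((ctc[, 1] - p[1])^2 + (ctc[, 2] - p[2])^2))))
    expect_lt(max(d1, d2), 1.5)
  }
})

test_that("measurement CSV writes 13 columns and round-trips at 2 decimals", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_measurements(list(), tmp)
  hdr <- readLines(tmp)
  expect_length(hdr, 1)
  expect_length(strsplit(hdr, ",")[[1]], 13)

  df <- data.frame(ear_tag = "A1", frame = 4L, posture = "head_down",
                   angle_deg = 2.847, bsl_px = 215.333, wh_px = 184.5, hh_px = 178.25,
                   cd_px = 119.126, bsl_cm = 67.29, wh_cm = 57.66, hh_cm = 55.7,
                   cd_cm = 37.2, flags = "")
  write_measurements(df, tmp)
  back <- read_measurements(tmp)
  expect_equal(nrow(back), 1)
  expect_equal(back$bsl_px, round(df$bsl_px, 2))
  expect_equal(back$angle_deg, round(df$angle_deg, 2))
  expect_equal(back$ear_tag, "A1")
})
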