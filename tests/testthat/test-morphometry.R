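# Landmark locators and the four pixel measures.

test_that("hip_point_headup takes the rearmost upper-half hull vertex", {
  # plain rectangle: the rear-top corner
  ct <- extract_contour(solid_mask(40, 20, at = c(2, 2), frame = c(48, 32)))
  expect_equal(hip_point_headup(ct, "left"), c(41, 2))
  expect_equal(hip_point_headup(ct, "right"), c(2, 2))

  # mirrored mask with flipped head side gives the mirrored point
  s <- make_silhouette(silhouette_params(head_pitch = 20), seed = 3)
  g <- matrix(as.logical(s$mask), nrow(s$mask), ncol(s$mask))
  mir <- binary_mask(g[, rev(seq_len(ncol(g)))])
  a <- hip_point_headup(extract_contour(s$mask), "left")
  b <- hip_point_headup(extract_contour(mir), "right")
  expect_equal(b[1], ncol(g) - 1 - a[1])
  expect_equal(b[2], a[2])
})

test_that("withers_point_headup maximizes the distance to line A", {
  # semicircular dip between the endpoints: the apex is returned
  th <- seq(0, pi, length.out = 50)
  dip <- cbind(50 + 30 * cos(th), 40 + 25 * sin(th))  # sags downward (y down)
  ct <- rbind(dip, c(20, 90), c(80, 90))              # return path below the dip
  w <- withers_point_headup(ct, c(80, 40), c(20, 40))
  expect_lt(abs(w[1] - 50), 3)
  expect_lt(abs(w[2] - 65), 2)

  # straight dorsal line: first arc point plus a warning flag
  rect <- extract_contour(solid_mask(30, 10, at = c(2, 2), frame = c(40, 20)))
  expect_warning(out <- withers_point_headup(rect, c(2, 2), c(31, 2)),
                 "straight")
  expect_equal(attr(out, "flag"), "flat_dorsal")

  expect_error(withers_point_headup(rect, c(2, 2), c(2, 2)), class = "validation_error")
})

test_that("dorsal_points_headdown finds the bump apexes inside their windows", {
  s <- make_silhouette(silhouette_params(head_pitch = -55), seed = 9)
  ct <- extract_contour(s$mask)
  dp <- dorsal_points_headdown(ct)
  expect_lt(landmark_err(dp$withers, s$landmarks$withers), 3)
  expect_lt(landmark_err(dp$hip, s$landmarks$hip), 3)
  expect_gt(dp$curvature[["withers"]], 0)

  # swapping the windows swaps the roles
  sw <- dorsal_points_headdown(ct, landmark_config(withers_window = c(6, 7) / 8,
                                                   hip_window = c(3, 4) / 8))
  expect_equal(sw$withers, dp$hip)
  expect_equal(sw$hip, dp$withers)

  # flat-backed rectangle: no convex curvature maximum
  rect <- extract_contour(solid_mask(60, 20, at = c(4, 4), frame = c(80, 32)))
  expect_error(dorsal_points_headdown(rect), class = "landmark_error")
})

test_that("bsl_points spans the inscribed-rectangle diagonal head-to-rear", {
  m <- solid_mask(40, 20, at = c(3, 5), frame = c(48, 32))
  b <- bsl_points(m, "left")
  expect_equal(b$length, sqrt(40^2 + 20^2))
  expect_equal(b$p1, c(3, 25))   # head-side lower corner
  expect_equal(b$p2, c(43, 5))   # rear upper corner
  br <- bsl_points(m, "right")
  expect_equal(br$p1, c(43, 25))
  expect_equal(br$length, b$length)

  # L-shaped mask: diagonal of the brute-force maximal rectangle
  g <- matrix(FALSE, 16, 16)
  g[2:5, 2:13] <- TRUE; g[2:13, 2:5] <- TRUE
  ref <- brute_max_rect(g)
  bl <- bsl_points(binary_mask(g), "left")
  expect_equal(bl$length, sqrt((ref[3] - ref[1])^2 + (ref[4] - ref[2])^2))
})

test_that("measure recovers rectangle geometry in closed form", {
  # 40 x 20 solid block resting on its lowest row; treat as head-up. The
  # head-top and shoulder coincide at the front corner, so line A is
  # degenerate and the withers collapses onto that corner, flagged.
  m <- solid_mask(40, 20, at = c(0, 12), frame = c(48, 32))
  rec <- measure(m, "head_up")
  expect_equal(rec$bsl_px, sqrt(40^2 + 20^2))
  expect_equal(rec$wh_px, 20)
  expect_equal(rec$hh_px, 20)
  expect_equal(rec$cd_px, 20)   # front-top corner to lower-front BSL corner
  expect_match(rec$flags, "degenerate_line_a")
})

test_that("measure refuses jump frames and unknown labels", {
  s <- make_silhouette(silhouette_params(body_tilt = 20), seed = 2)
  expect_error(measure(s$mask, "jump"), class = "unsupported_posture_error")
  expect_error(measure(s$mask, "sitting"), class = "validation_error")
})

test_that("measure matches generator truth on both walking postures", {
  for (pitch in c(-55, 20)) {
    s <- make_silhouette(silhouette_params(head_pitch = pitch), seed = 11)
    rec <- measure(s$mask, classify_posture(s$mask))
    tm <- s$measures_px
    expect_lt(landmark_err(rec$landmarks$withers, s$landmarks$withers), 3)
    expect_lt(landmark_err(rec$landmarks$hip, s$landmarks$hip), 3)
    expect_lt(landmark_err(rec$landmarks$head, s$landmarks$head), 3)
    expect_lt(abs(rec$wh_px - tm[["WH"]]), 5)
    expect_lt(abs(rec$hh_px - tm[["HH"]]), 5)
    expect_lt(abs(rec$bsl_px - tm[["BSL"]]) / tm[["BSL"]], 0.05)
    expect_lt(abs(rec$cd_px - tm[["CD"]]) / tm[["CD"]], 0.15)
  }
})

test_that("measures are translation invariant and scale with 2x upsampling", {
  s <- make_silhouette(silhouette_params(head_pitch = -55), seed = 13)
  pr <- classify_posture(s$mask)
  rec <- measure(s$mask, pr)

  g <- matrix(as.logical(s$mask), nrow(s$mask), ncol(s$mask))
  idx <- which(g, arr.ind = TRUE)
  shifted <- matrix(FALSE, nrow(g), ncol(g))
  shifted[cbind(idx[, 1] - 9, idx[, 2] + 13)] <- TRUE
  rec_t <- measure(binary_mask(shifted), pr)
  for (f in c("bsl_px", "wh_px", "hh_px", "cd_px")) {
    expect_equal(rec_t[[f]], rec[[f]], tolerance = 1e-9)
  }

  big <- binary_mask(g[rep(seq_len(nrow(g)), each = 2), rep(seq_len(ncol(g)), each = 2)])
  rec_2 <- measure(big, pr)
  for (f in c("bsl_px", "wh_px", "hh_px", "cd_px")) {
    expect_lt(abs(rec_2[[f]] - 2 * rec[[f]]), 3)
  }
})

test_that("mirroring the mask and flipping head_side leaves measures unchanged", {
  s <- make_silhouette(silhouette_params(head_pitch = -55), seed = 14)
  pr <- classify_posture(s$mask)
  g <- matrix(as.logical(s$mask), nrow(s$mask), ncol(s$mask))
  mir <- binary_mask(g[, rev(seq_len(ncol(g)))])
  a <- measure(s$mask, pr, head_side = "left")
  b <- measure(mir, pr, head_side = "right")
  for (f in c("bsl_px", "wh_px", "hh_px", "cd_px")) {
    expect_lt(abs(a[[f]] - b[[f]]), 1)
  }
})

test_that("fixed-row ground mode and the alternate chest corner are honored", {
  s <- make_silhouette(silhouette_params(head_pitch = -55), seed = 15)
  pr <- classify_posture(s$mask)
  base <- measure(s$mask, pr)
  fixed <- measure(s$mask, pr,
                   landmark_config(ground_mode = "fixed_row",
                                   ground_row = base$landmarks$ground_y + 10))
  expect_equal(fixed$wh_px, base$wh_px + 10)
  expect_equal(fixed$hh_px, base$hh_px + 10)

  alt <- measure(s$mask, pr, landmark_config(cd_corner = "upper"))
  expect_equal(alt$cd_px,
               landmark_err(base$landmarks$withers, base$landmarks$bsl_p2))
})
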