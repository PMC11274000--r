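# Pure geometric primitives the pipeline statistics are built from.
# Points are rows of (x, y) matrices, 0-based pixel coordinates, y down.

pt_dist <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

#' Convex hull of a point set
#'
#' Hull vertices in clockwise traversal order (viewed with y growing
#' downward); collinear points interior to hull edges are not retained.
#'
#' @param points an `n x 2` matrix of `(x, y)` coordinates, n >= 3, not all
#'   collinear.
#' @return an `m x 2` matrix of hull vertices.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) ovi_stop("need at least 3 points", "degenerate_geometry_error")
  idx <- grDevices::chull(points[, 1], points[, 2])
  if (length(idx) < 3L) {
    ovi_stop("points are collinear: convex hull is degenerate", "degenerate_geometry_error")
  }
  # chull is clockwise for y-up display; reverse for our y-down convention
  hull <- points[rev(idx), , drop = FALSE]
  # defensively drop any exactly collinear triple
  keep <- rep(TRUE, nrow(hull))
  n <- nrow(hull)
  for (i in seq_len(n)) {
    a <- hull[(i - 2L) %% n + 1L, ]; b <- hull[i, ]; cc <- hull[i %% n + 1L, ]
    cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
    if (cr == 0) keep[i] <- FALSE
  }
  hull <- hull[keep, , drop = FALSE]
  if (nrow(hull) < 3L) {
    ovi_stop("points are collinear: convex hull is degenerate", "degenerate_geometry_error")
  }
  colnames(hull) <- c("x", "y")
  hull
}

#' Minimum-area enclosing (rotated) rectangle
#'
#' Rotating calipers over the convex-hull edges: the optimal rectangle has a
#' side collinear with a hull edge. When several orientations tie in area
#' (within 1e-9), the orientation with the smallest absolute long-side angle
#' wins.
#'
#' @param points an `n x 2` matrix, n >= 3, not all collinear.
#' @return a `rotated_rect`: list with `center`, `long_side`, `short_side`,
#'   `angle_deg` (orientation of the long side vs the image horizontal, in
#'   `[-90, 90)`).
#' @export
min_area_rect <- function(points) {
  hull <- convex_hull(points)
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[i %% n + 1L, ]
    th <- atan2(b[2] - a[2], b[1] - a[1])
    ct <- cos(th); st <- sin(th)
    xr <- hull[, 1] * ct + hull[, 2] * st
    yr <- -hull[, 1] * st + hull[, 2] * ct
    wd <- max(xr) - min(xr); ht <- max(yr) - min(yr)
    area <- wd * ht
    phi <- if (wd >= ht) th else th + pi / 2
    ang <- ((phi * 180 / pi + 90) %% 180) - 90
    cand <- list(
      area = area, angle_deg = ang,
      long_side = max(wd, ht), short_side = min(wd, ht),
      cx_r = (min(xr) + max(xr)) / 2, cy_r = (min(yr) + max(yr)) / 2,
      th = th
    )
    if (is.null(best) ||
        area < best$area - 1e-9 ||
        (abs(area - best$area) <= 1e-9 && abs(ang) < abs(best$angle_deg))) {
      best <- cand
    }
  }
  center <- c(best$cx_r * cos(best$th) - best$cy_r * sin(best$th),
              best$cx_r * sin(best$th) + best$cy_r * cos(best$th))
  structure(list(center = unname(center),
                 long_side = unname(best$long_side),
                 short_side = unname(best$short_side),
                 angle_deg = unname(best$angle_deg)),
            class = "rotated_rect")
}

#' Corners of a rotated rectangle
#' @param rect a `rotated_rect` from [min_area_rect()].
#' @return a `4 x 2` matrix of corner coordinates.
#' @export
rect_corners <- function(rect) {
  th <- rect$angle_deg * pi / 180
  u <- c(cos(th), sin(th)) * rect$long_side / 2
  v <- c(-sin(th), cos(th)) * rect$short_side / 2
  corners <- rbind(rect$center - u - v, rect$center + u - v,
                   rect$center + u + v, rect$center - u + v)
  colnames(corners) <- c("x", "y")
  corners
}

#' Tight axis-aligned bounding rectangle
#'
#' Half-open pixel bounds: the maximum coordinate side is exclusive, so for
#' integer pixel coordinates a single point `(5, 5)` yields `(5, 5, 6, 6)`.
#'
#' @param points an `n x 2` matrix, n >= 1.
#' @return named numeric `c(x0, y0, x1, y1)` of class `axis_rect`.
#' @export
bounding_rect <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) ovi_stop("need at least one point", "validation_error")
  structure(c(x0 = min(points[, 1]), y0 = min(points[, 2]),
              x1 = max(points[, 1]) + 1, y1 = max(points[, 2]) + 1),
            class = "axis_rect")
}

#' Maximal axis-aligned all-foreground rectangle
#'
#' The largest axis-aligned rectangle consisting entirely of foreground
#' pixels, found with the per-row histogram / monotonic-stack algorithm
#' (linear in the pixel count). Ties in area are broken by the smallest
#' `(y0, x0)`.
#'
#' @param mask a non-empty [binary_mask()].
#' @return named numeric `c(x0, y0, x1, y1)` (half-open bounds) of class
#'   `axis_rect`, with the area as attribute `area`.
#' @export
max_inscribed_rect <- function(mask) {
  if (!any(mask)) ovi_stop("mask is empty", "empty_mask_error")
  res <- max_rect_stack(as_grid(mask))
  structure(c(x0 = res[1], y0 = res[2], x1 = res[3], y1 = res[4]),
            class = "axis_rect", area = res[5])
}

#' U-chord-length curvature at a contour point
#'
#' Discrete signed curvature from the chord between the two contour
#' neighbors located at Euclidean distance `U` from position `i`, one
#' walking backward (`p_ib`) and one forward (`p_if`). With
#' `D = |p_ib - p_if|` the curvature is
#' `c = s * sqrt(max(0, 1 - D^2 / (4 U^2)))`, where the sign `s` is the
#' turn direction of the triple `(p_ib, p_i, p_if)` (positive for a convex
#' prominence on the dorsal outline of a clockwise-traced contour);
#' `c = 0` for exactly collinear triples. `|c|` tends to 0 on straight runs
#' and to 1 at a hairpin.
#'
#' Neighbor selection walks along the contour polyline until the Euclidean
#' distance from `p_i` first reaches `U` and places the endpoint exactly at
#' distance `U` by linear interpolation on the crossing segment; vertex
#' snapping would bias `|c|` on coarsely sampled contours, where no vertex
#' sits at exactly distance `U`. If the walk never reaches distance `U`
#' (a contour smaller than the chord), the farthest reachable vertex is
#' used and the radicand is normalized by the realized span instead.
#'
#' @param contour a `contour` matrix from [extract_contour()] (>= 5 points).
#' @param i 1-based contour position.
#' @param U chord-length constant in pixels (> 0).
#' @return a `curvature_sample`: list with `index`, `c`, `s`, `D`, `p_ib`,
#'   `p_if`, `U`.
#' @export
u_chord_curvature <- function(contour, i, U) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (n < 5L) ovi_stop("contour must have at least 5 points", "validation_error")
  if (!is.numeric(U) || U <= 0) ovi_stop("U must be positive", "validation_error")
  if (i < 1L || i > n) ovi_stop("contour index out of range", "validation_error")
  pi_ <- contour[i, ]
  walk <- function(dir) {
    kmax <- n %/% 2L
    steps <- seq_len(kmax)
    idxs <- ((i - 1L + dir * steps) %% n) + 1L
    ds <- sqrt((contour[idxs, 1] - pi_[1])^2 + (contour[idxs, 2] - pi_[2])^2)
    kc <- which(ds >= U)[1]
    if (is.na(kc)) {
      # contour smaller than the chord: farthest reachable vertex
      k <- max(which(ds == max(ds)))
      return(list(p = as.numeric(contour[idxs[k], ]), d = ds[k]))
    }
    a <- if (kc == 1L) pi_ else contour[idxs[kc - 1L], ]
    b <- contour[idxs[kc], ]
    # point on segment a->b at Euclidean distance U from p_i
    v <- as.numeric(b - a); w0 <- as.numeric(a - pi_)
    qa <- sum(v^2); qb <- 2 * sum(v * w0); qc <- sum(w0^2) - U^2
    disc <- max(0, qb^2 - 4 * qa * qc)
    t <- (-qb + sqrt(disc)) / (2 * qa)
    t <- min(1, max(0, t))
    list(p = as.numeric(a) + t * v, d = U)
  }
  wb <- walk(-1L); wf <- walk(+1L)
  pb <- wb$p; pf <- wf$p
  D <- pt_dist(pb, pf)
  s <- sign((pi_[1] - pb[1]) * (pf[2] - pb[2]) - (pf[1] - pb[1]) * (pi_[2] - pb[2]))
  denom <- wb$d + wf$d  # 2U unless the contour is smaller than the chord
  cval <- if (denom <= 0) 0 else s * sqrt(max(0, 1 - D^2 / denom^2))
  structure(list(index = i, c = cval, s = s, D = D,
                 p_ib = as.numeric(pb), p_if = as.numeric(pf), U = U),
            class = "curvature_sample")
}

#' Curvature profile over selected contour positions
#' @param contour a `contour` matrix (>= 5 points).
#' @param U chord-length constant in pixels.
#' @param indices 1-based contour positions (default: all).
#' @return data frame with columns `index` and `c`.
#' @export
contour_curvature <- function(contour, U, indices = seq_len(nrow(contour))) {
  cs <- vapply(indices, function(i) u_chord_curvature(contour, i, U)$c, numeric(1))
  data.frame(index = indices, c = cs)
}

#' Perpendicular distance from a point to an infinite line
#' @param p query point `(x, y)`.
#' @param a,b two distinct points defining the line.
#' @return distance in pixels.
#' @export
point_line_distance <- function(p, a, b) {
  p <- as.numeric(p); a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == b)) ovi_stop("line endpoints must be distinct", "validation_error")
  abs((b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])) / pt_dist(a, b)
}
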