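# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive search, per-pixel loops, closed forms) so they share
# no code path with the implementation they check.

# exhaustive maximal all-true rectangle with the (area, y0, x0) tie-break;
# uses a summed-area table so the all-true check is O(1) per candidate
brute_max_rect <- function(g) {
  h <- nrow(g); w <- ncol(g)
  sat <- matrix(0, h + 1, w + 1)
  sat[-1, -1] <- apply(apply(g * 1, 2, cumsum), 1, cumsum) |> t()
  rect_sum <- function(y0, x0, y1, x1)
    sat[y1 + 1, x1 + 1] - sat[y0, x1 + 1] - sat[y1 + 1, x0] + sat[y0, x0]
  best <- c(0, 0, 0, 0, 0)
  for (y0 in seq_len(h)) for (x0 in seq_len(w)) {
    if (!g[y0, x0]) next
    for (y1 in y0:h) for (x1 in x0:w) {
      a <- (y1 - y0 + 1) * (x1 - x0 + 1)
      if (rect_sum(y0, x0, y1, x1) == a) {
        better <- a > best[5] ||
          (a == best[5] && a > 0 &&
             (y0 - 1 < best[2] || (y0 - 1 == best[2] && x0 - 1 < best[1])))
        if (better) best <- c(x0 - 1, y0 - 1, x1, y1, a)
      }
    }
  }
  best
}

# even-odd point-in-polygon test for a single point (scalar ray crossing)
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- poly[i, 1] + (py - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# per-pixel weighted-region score (loops over every pixel once)
frame_score_oracle <- function(mask, w) {
  g <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  wd <- ncol(g); ht <- nrow(g)
  total <- 0
  for (yy in 0:(ht - 1)) for (xx in 0:(wd - 1)) {
    if (!g[yy + 1, xx + 1]) next
    for (i in 1:3) {
      r <- w$regions[[i]]
      if (xx >= floor(r[1] * wd) && xx < floor(r[2] * wd) &&
          yy >= floor(r[3] * ht) && yy < floor(r[4] * ht)) {
        total <- total + w$n[i]
      }
    }
  }
  total
}

rotate_pts <- function(pts, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  px <- pts[, 1] - center[1]; py <- pts[, 2] - center[2]
  cbind(px * cos(th) - py * sin(th) + center[1],
        px * sin(th) + py * cos(th) + center[2])
}

circle_contour <- function(n = 360, r = 50, cx = 100, cy = 100) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

solid_mask <- function(width, height, at = c(0, 0), frame = c(width, height)) {
  g <- matrix(FALSE, frame[2], frame[1])
  g[at[2] + seq_len(height), at[1] + seq_len(width)] <- TRUE
  binary_mask(g)
}

# study-condition draws for the measurement suites: level, noise-free
# walking animals with mild anatomic variation
sample_measure_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    silhouette_params(
      torso_length = runif(1, 275, 305), torso_depth = runif(1, 106, 118),
      leg_length = runif(1, 80, 90), neck_length = runif(1, 110, 120),
      head_pitch = sample(c(-55, 20), 1))
  })
}

landmark_err <- function(a, b) sqrt(sum((a - b)^2))
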