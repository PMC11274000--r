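# Parametric side-view quadruped silhouettes with known ground truth.
# The generator composes simple primitives in a body frame -- torso ellipse,
# two leg slabs, a sagging neck band ending in a head disk, a rump
# prominence and two dorsal bumps (the scapula and hip-bone protrusions the
# curvature landmarks key on) -- then applies whole-body tilt. All truth
# (landmarks, posture label, measures) is computed from the generative
# geometry, never from the measurement pipeline, so it can serve as an
# independent oracle.

#' Silhouette generator parameters
#'
#' Defaults emulate an adult sheep at the channel camera's 640 x 480
#' resolution (about 3 px per cm): torso 290 x 112 px, legs 85 px,
#' neck 115 px. `head_pitch` is the neck elevation in degrees (negative =
#' lowered head); `body_tilt` rotates the whole body, lifting the head side,
#' as happens mid-jump. A tilt above 12 degrees generates a jumping animal,
#' whose head is always raised (sheep jump head-up).
#'
#' @param torso_length,torso_depth torso ellipse axes in px.
#' @param leg_length leg extent below the torso in px.
#' @param leg_flexion rearward leg slant in degrees.
#' @param neck_length,head_pitch neck extent (px) and elevation (degrees).
#' @param body_tilt whole-body rotation in degrees (head side up).
#' @param dorsal_bump_amplitude radius in px of the withers/hip prominences.
#' @param boundary_noise amplitude in px of smooth low-frequency boundary
#'   perturbation of the torso outline (0 = clean).
#' @param resolution frame size `c(width, height)` in px.
#' @param head_side which image side the head faces.
#' @return a `silhouette_params` list.
#' @export
silhouette_params <- function(torso_length = 290, torso_depth = 112,
                              leg_length = 85, leg_flexion = 15,
                              neck_length = 115, head_pitch = -55,
                              body_tilt = 0, dorsal_bump_amplitude = 13,
                              boundary_noise = 0,
                              resolution = c(640, 480),
                              head_side = c("left", "right")) {
  p <- list(torso_length = torso_length, torso_depth = torso_depth,
            leg_length = leg_length, leg_flexion = leg_flexion,
            neck_length = neck_length, head_pitch = head_pitch,
            body_tilt = body_tilt,
            dorsal_bump_amplitude = dorsal_bump_amplitude,
            boundary_noise = boundary_noise,
            resolution = as.integer(resolution),
            head_side = match.arg(head_side))
  lens <- c(torso_length, torso_depth, leg_length, neck_length, dorsal_bump_amplitude)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    ovi_stop("all lengths must be positive", "validation_error")
  }
  if (any(p$resolution < 32L)) ovi_stop("resolution too small", "validation_error")
  structure(p, class = "silhouette_params")
}

# fixed body-frame layout (fractions of the torso semi-axes)
.sil_geom <- function(p) {
  w <- p$resolution[1]; h <- p$resolution[2]
  a <- p$torso_length / 2; b <- p$torso_depth / 2
  cx <- w / 2; cy <- h / 2
  tilt <- p$body_tilt
  jump <- tilt > 12
  # jumping sheep throw the head up high regardless of their walking pitch
  pitch <- if (jump) 55 else p$head_pitch
  pr <- pitch * pi / 180
  B <- c(cx - 0.92 * a, cy - 0.45 * b)           # neck base (inside torso)
  u <- c(cos(pr), sin(pr))                       # neck axis, head end -> base
  H <- B - p$neck_length * u                     # head center
  n <- c(sin(pr), -cos(pr))                      # dorsal normal of the neck
  rh <- 28; wn <- 17; sag <- 22                  # head radius, neck half-width, dorsal sag
  # the neck band runs past its base, tapering to zero width where the
  # sagging dorsal edge meets the ventral edge, so it dives under the torso
  # outline (the withers junction) without leaving a hanging sliver
  t_end <- sqrt(2 * 17 / 22)
  nose <- 6; tail <- 6   # pointed muzzle / ischium wedges: unique extreme points
  # rump center stays inside the ellipse (0.82^2 + 0.55^2 < 1) so the
  # prominence never detaches from the torso at small body sizes
  rump <- c(cx + 0.82 * a, cy - 0.55 * b); rk <- 24
  leg_top <- cy + 0.6 * b
  ground <- leg_top + p$leg_length
  xmin <- min(H[1] - rh - nose, cx - a)
  xmax <- max(cx + a, rump[1] + rk + tail)
  S <- xmax - xmin
  rb <- p$dorsal_bump_amplitude
  # dorsal prominences: upright ellipses (tight tip radius 0.3*rb) so the
  # curvature maximum is unique at the apex
  bump_sx <- 0.6 * rb; bump_sy <- 1.2 * rb
  bump_x <- xmin + c(3.5, 6.5) / 8 * S
  if (any(abs(bump_x - cx) > 0.97 * a)) {
    ovi_stop("dorsal bumps fall outside the torso; adjust proportions", "validation_error")
  }
  list(w = w, h = h, a = a, b = b, cx = cx, cy = cy, tilt = tilt, jump = jump,
       pitch = pitch, B = B, H = H, u = u, n = n, rh = rh, wn = wn, sag = sag,
       t_end = t_end, nose = nose, tail = tail,
       rump = rump, rk = rk, leg_top = leg_top, ground = ground,
       xmin = xmin, xmax = xmax, S = S, rb = rb,
       bump_sx = bump_sx, bump_sy = bump_sy, bump_x = bump_x)
}

ellipse_top_y <- function(g, x) {
  dxn <- (x - g$cx) / g$a
  ifelse(abs(dxn) < 1, g$cy - g$b * sqrt(pmax(0, 1 - dxn^2)), NA_real_)
}

# dorsal neck edge point at band parameter t in [0, 1] (0 = head end)
.neck_edge <- function(g, t) {
  off <- g$wn - g$sag * t^2
  cbind(g$H[1] + t * sqrt(sum((g$B - g$H)^2)) * g$u[1] + off * g$n[1],
        g$H[2] + t * sqrt(sum((g$B - g$H)^2)) * g$u[2] + off * g$n[2])
}

# neck-torso dorsal junction: where the sagging neck edge dives under the
# ellipse top (the anatomical withers of a raised neck)
.neck_junction <- function(g) {
  ts <- seq(0, g$t_end, length.out = 1001)
  e <- .neck_edge(g, ts)
  top <- ellipse_top_y(g, e[, 1])
  d <- e[, 2] - top                       # positive once the edge is below the top
  ok <- which(!is.na(d))
  if (length(ok) < 2L) ovi_stop("neck never meets the torso outline", "validation_error")
  cross <- ok[which(d[ok] >= 0)[1]]
  if (is.na(cross)) ovi_stop("neck never meets the torso outline", "validation_error")
  lo <- ts[max(cross - 1L, 1L)]; hi <- ts[cross]
  f <- function(t) { e <- .neck_edge(g, t); e[1, 2] - ellipse_top_y(g, e[1, 1]) }
  t0 <- tryCatch(stats::uniroot(f, c(lo, hi))$root, error = function(e) hi)
  as.numeric(.neck_edge(g, t0))
}

.rot_fwd <- function(pts, theta_deg, center) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(t(R %*% t(sweep(pts, 2, center))), 2, center, `+`)
}

#' Generate a silhouette with ground truth
#'
#' Deterministic given `(params, seed)`. The returned truth landmarks and
#' pixel measures come from the generative geometry: dorsal bump apexes
#' (head-down withers/hip), the neck-torso dorsal junction (head-up
#' withers), the rump prominence extreme (head-up hip), the nose tip, and
#' closed forms on the torso ellipse for the slant-length diagonal. Jump
#' silhouettes carry `NA` measures (jumping frames are never measured).
#'
#' @param params a [silhouette_params()].
#' @param seed integer seed for the boundary-noise harmonics.
#' @return a `silhouette_truth`: list with `mask`, `landmarks`, `posture`,
#'   `measures_px`, `params`.
#' @export
make_silhouette <- function(params = silhouette_params(), seed = 1) {
  if (!inherits(params, "silhouette_params")) params <- do.call(silhouette_params, params)
  g <- .sil_geom(params)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ph <- stats::runif(2, 0, 2 * pi)  # noise phases (drawn even when unused)

  w <- g$w; h <- g$h
  X <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  Y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  if (params$head_side == "right") X <- (w - 1) - X
  if (g$tilt != 0) {
    th <- -g$tilt * pi / 180  # inverse rotation into the body frame
    Xc <- X - g$cx; Yc <- Y - g$cy
    Xb <- cos(th) * Xc - sin(th) * Yc + g$cx
    Yb <- sin(th) * Xc + cos(th) * Yc + g$cy
  } else { Xb <- X; Yb <- Y }

  dx <- (Xb - g$cx) / g$a; dy <- (Yb - g$cy) / g$b
  r <- sqrt(dx^2 + dy^2)
  lim <- 1
  if (params$boundary_noise > 0) {
    phi <- atan2(dy, dx)
    lim <- 1 + (params$boundary_noise / g$b) *
      (0.6 * sin(3 * phi + ph[1]) + 0.4 * sin(7 * phi + ph[2]))
  }
  mask <- r <= lim

  # legs: slabs below the torso, shearing rearward (flexion) only below the
  # belly line so the torso-band cross-section stays vertical
  shear_tot <- 0.5 * params$leg_length * sin(params$leg_flexion * pi / 180)
  belly <- g$cy + g$b
  free <- max(1, g$ground - belly)
  for (lx in c(g$cx - 0.6 * g$a, g$cx + 0.6 * g$a)) {
    tly <- (Yb - g$leg_top) / params$leg_length
    xc <- lx + shear_tot * pmax(0, (Yb - belly) / free)
    mask <- mask | (tly >= 0 & tly <= 1 & abs(Xb - xc) <= 12)
  }

  # neck band with dorsal sag, plus head disk and pointed muzzle
  L <- params$neck_length
  tpar <- ((Xb - g$H[1]) * g$u[1] + (Yb - g$H[2]) * g$u[2]) / L
  q <- (Xb - g$H[1]) * g$n[1] + (Yb - g$H[2]) * g$n[2]
  mask <- mask | (tpar >= 0 & tpar <= g$t_end & q >= -g$wn & q <= g$wn - g$sag * tpar^2)
  mask <- mask | ((Xb - g$H[1])^2 + (Yb - g$H[2])^2 <= g$rh^2)
  ntip <- g$H[1] - g$rh - g$nose
  mask <- mask | (Xb >= ntip & Xb <= g$H[1] & abs(Yb - g$H[2]) <= 0.6 * (Xb - ntip))

  # rump prominence with pointed rear wedge, and the two dorsal bumps
  mask <- mask | ((Xb - g$rump[1])^2 + (Yb - g$rump[2])^2 <= g$rk^2)
  ttip <- g$rump[1] + g$rk + g$tail
  mask <- mask | (Xb <= ttip & Xb >= g$rump[1] & abs(Yb - g$rump[2]) <= 0.6 * (ttip - Xb))
  for (bx in g$bump_x) {
    by <- ellipse_top_y(g, bx)
    mask <- mask | (((Xb - bx) / g$bump_sx)^2 + ((Yb - by) / g$bump_sy)^2 <= 1)
  }

  if (any(mask[c(1, h), ]) || any(mask[, c(1, w)])) {
    ovi_stop("silhouette exceeds the frame; shrink the body or reduce tilt", "validation_error")
  }

  # thin tapers can rasterize to isolated slivers of a few pixels; drop
  # them, but treat anything larger as a genuinely disconnected body part
  bm <- binary_mask(mask)
  lab <- label_components8(bm)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    if (sum(sizes) - max(sizes) > 10L) {
      ovi_stop("generated silhouette is disconnected; adjust proportions", "validation_error")
    }
    bm <- binary_mask(lab == which.max(sizes))
  }

  # ---- truth ----
  posture <- if (g$jump) "jump" else if (g$pitch > 0) "head_up" else "head_down"
  bump_apex <- cbind(g$bump_x, ellipse_top_y(g, g$bump_x) - g$bump_sy)
  if (posture == "head_down") {
    withers <- bump_apex[1, ]; hip <- bump_apex[2, ]
  } else {
    withers <- .neck_junction(g)
    hip <- c(g$rump[1] + g$rk + g$tail, g$rump[2])
  }
  head <- c(g$H[1] - g$rh - g$nose, g$H[2])
  # lowest point of the (possibly tilted) body: rotated leg-slab bottom
  # corners, head/rump disk extremes and the torso-ellipse support line
  th <- g$tilt * pi / 180
  shear_tot <- 0.5 * params$leg_length * sin(params$leg_flexion * pi / 180)
  leg_corners <- do.call(rbind, lapply(c(g$cx - 0.6 * g$a, g$cx + 0.6 * g$a), function(lx)
    cbind(lx + shear_tot + c(-12, 12), g$ground)))
  low <- rbind(leg_corners, c(g$H[1], g$H[2]), c(g$rump[1], g$rump[2]))
  low_r <- if (g$tilt != 0) .rot_fwd(low, g$tilt, c(g$cx, g$cy)) else low
  ground_cont <- max(low_r[1:4, 2],
                     low_r[5, 2] + g$rh,
                     low_r[6, 2] + g$rk,
                     g$cy + sqrt((g$a * sin(th))^2 + (g$b * cos(th))^2))
  ground_y <- floor(ground_cont) + 1       # half-open bottom bound of the lowest row
  # maximal inscribed rectangle of the generative shape, closed form over the
  # two candidate configurations: the bare torso-ellipse rectangle and the
  # leg-to-leg rectangle (the vertical leg slabs let the rectangle span the
  # full inter-leg width down to the belly outline at the inner leg edges)
  s2 <- sqrt(2) / 2
  cand_e <- c(g$cx - g$a * s2, g$cy - g$b * s2, g$cx + g$a * s2, g$cy + g$b * s2)
  out_off <- 0.6 * g$a + 12; in_off <- 0.6 * g$a - 12
  ytop_l <- g$cy - g$b * sqrt(max(0, 1 - (out_off / g$a)^2))
  ybot_l <- g$cy + g$b * sqrt(max(0, 1 - (in_off / g$a)^2))
  cand_l <- c(g$cx - out_off, ytop_l, g$cx + out_off, ybot_l)
  area <- function(r) (r[3] - r[1]) * (r[4] - r[2])
  rect <- if (area(cand_l) >= area(cand_e)) cand_l else cand_e
  bsl_p1 <- c(rect[1], rect[4])
  bsl_p2 <- c(rect[3], rect[2])
  measures <- c(BSL = sqrt(sum((bsl_p2 - bsl_p1)^2)),
                WH = ground_y - withers[2],
                HH = ground_y - hip[2],
                CD = sqrt(sum((withers - bsl_p1)^2)))
  if (posture == "jump") measures[] <- NA_real_

  pts <- rbind(withers = withers, hip = hip, head = head,
               bsl_p1 = bsl_p1, bsl_p2 = bsl_p2)
  if (g$tilt != 0) pts <- .rot_fwd(pts, g$tilt, c(g$cx, g$cy))
  if (params$head_side == "right") pts[, 1] <- (w - 1) - pts[, 1]
  landmarks <- c(lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
                 list(ground_y))
  names(landmarks) <- c(rownames(pts), "ground_y")

  structure(list(mask = bm, landmarks = landmarks,
                 posture = posture, measures_px = measures,
                 params = params, seed = seed),
            class = "silhouette_truth")
}

#' @export
print.silhouette_truth <- function(x, ...) {
  cat(sprintf("<silhouette_truth %s, %d px>\n", x$posture, mask_area(x$mask)))
  invisible(x)
}

#' Sample silhouette parameters emulating a channel population
#'
#' Draws per-animal generator parameters mirroring what a capture channel
#' sees. Postures follow the field proportions (about 66% head-down, 17%
#' head-up, 17% jumping). Walking animals are near-level: their body tilt is
#' half-normal (s.d. 3 degrees, truncated at 9) because centered key frames
#' catch mid-stride, level bodies; jumping animals tilt strongly (uniform
#' 14-24 degrees). The resulting rectangle-angle statistic distributions
#' track the ones reported on real channel passes (walking about 3 +/- 2
#' degrees, jumps well separated).
#'
#' Anatomy varies about 5% around the defaults;
#' boundary noise of 1 px emulates segmentation roughness.
#'
#' @param n number of animals.
#' @param seed RNG seed.
#' @param boundary_noise passed to [silhouette_params()].
#' @return list of `n` [silhouette_params()] objects.
#' @export
sample_channel_params <- function(n, seed = 1, boundary_noise = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    posture <- sample(c("head_down", "head_up", "jump"), 1,
                      prob = c(0.657, 0.168, 0.175))
    tilt <- if (posture == "jump") {
      stats::runif(1, 14, 24)
    } else {
      repeat { t0 <- abs(stats::rnorm(1, 0, 3)); if (t0 <= 9) break }
      t0
    }
    silhouette_params(
      torso_length = stats::runif(1, 275, 305),
      torso_depth = stats::runif(1, 106, 118),
      leg_length = stats::runif(1, 80, 90),
      neck_length = stats::runif(1, 110, 120),
      head_pitch = if (posture == "head_up") 20 else -55,
      body_tilt = tilt,
      boundary_noise = boundary_noise)
  })
}

#' Generate a channel-pass frame sequence
#'
#' The silhouette sweeps horizontally across the frame (clipped at the
#' borders); the middle frame `floor(n_frames / 2)` (0-based) is centered,
#' so a correct key-frame selector must return it.
#'
#' @param params a [silhouette_params()].
#' @param n_frames number of frames (>= 1).
#' @param seed generator seed.
#' @return a [frame_sequence()] with attribute `truth` (list with
#'   `true_key_index` and the base `silhouette_truth`).
#' @export
make_walk_sequence <- function(params = silhouette_params(), n_frames = 9, seed = 1) {
  if (n_frames < 1) ovi_stop("need at least one frame", "validation_error")
  base <- make_silhouette(params, seed)
  g <- as_grid(base$mask)
  w <- ncol(g); h <- nrow(g)
  mid <- n_frames %/% 2L
  step <- max(1L, w %/% (n_frames + 1L))
  frames <- lapply(seq_len(n_frames) - 1L, function(k) {
    dx <- (k - mid) * step
    out <- matrix(FALSE, h, w)
    src <- intersect(seq_len(w), seq_len(w) - dx)
    if (length(src) > 0L) out[, src + dx] <- g[, src]
    list(index = k, mask = binary_mask(out))
  })
  seq <- frame_sequence("synthetic", "side", frames)
  attr(seq, "truth") <- list(true_key_index = mid, base = base)
  seq
}

#' Generate calibration-plate observations from a ratio model
#'
#' Emulates a plate sweep: the first predictor steps across the calibrated
#' range in 5-cm increments (11 levels for the side plate's 0-50 cm, 19 for
#' the back plate's 0-90 cm) at a few camera distances, with optional
#' Gaussian noise on the observed ratios.
#'
#' @param model a [calibration_model()].
#' @param u_values plate positions in cm; default: the model's calibrated
#'   range in 5-cm steps (0-50 cm when the model carries no range).
#' @param v_values camera-distance levels in cm.
#' @param noise_sd Gaussian noise s.d. on the ratios.
#' @param seed RNG seed.
#' @return data frame with columns `u`, `v`, `ratio`.
#' @export
make_calibration_samples <- function(model, u_values = NULL,
                                     v_values = seq(100, 200, by = 25),
                                     noise_sd = 0, seed = 1) {
  if (is.null(u_values)) {
    rng <- model$range_u %||% c(0, 50)
    u_values <- seq(rng[1], rng[2], by = 5)
  }
  grid <- expand.grid(u = u_values, v = v_values)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  grid$ratio <- eval_ratio(model, grid$u, grid$v) + stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}
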