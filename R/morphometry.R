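# Anatomical landmark detection and the four pixel measurements:
# body slanting length (BSL), withers height (WH), hip height (HH) and
# chest depth (CD). Landmark sources switch on posture: with the head
# raised the hip comes from the convex hull and the withers from the
# line-A distance rule; with the head lowered both dorsal points come from
# U-chord curvature maxima inside fractional windows of the body extent.

#' Landmark detection configuration
#'
#' @param withers_window,hip_window fractional windows of the horizontal
#'   extent `S`, measured from the head-side boundary, searched for the
#'   dorsal curvature maxima in the head-down posture. Defaults `[3/8, 4/8]`
#'   (withers, anatomically forward) and `[6/8, 7/8]` (hip).
#' @param U_px U-chord-length constant in pixels; `NULL` (default) scales
#'   with the silhouette: `max(5, round(0.05 * S))`.
#' @param ground_mode `"mask_bottom"` (ground = bottom of the lowest
#'   foreground row, the hoof contact line) or `"fixed_row"` (a known
#'   channel-floor row, robust to a hoof raised mid-stride).
#' @param ground_row required when `ground_mode = "fixed_row"`.
#' @param cd_corner which inscribed-rectangle corner ends the chest-depth
#'   segment: `"lower"` (head-side lower corner, the sternum reading;
#'   default) or `"upper"` (rear upper corner).
#' @return a `landmark_config`.
#' @export
landmark_config <- function(withers_window = c(3, 4) / 8,
                            hip_window = c(6, 7) / 8,
                            U_px = NULL,
                            ground_mode = c("mask_bottom", "fixed_row"),
                            ground_row = NULL,
                            cd_corner = c("lower", "upper")) {
  ground_mode <- match.arg(ground_mode)
  for (wnd in list(withers_window, hip_window)) {
    if (length(wnd) != 2L || any(wnd < 0) || any(wnd > 1) || wnd[1] >= wnd[2]) {
      ovi_stop("windows must be increasing fractions within [0, 1]", "validation_error")
    }
  }
  if (withers_window[2] > hip_window[1] && hip_window[2] > withers_window[1]) {
    ovi_stop("withers and hip windows must not overlap", "validation_error")
  }
  if (!is.null(U_px) && U_px < 2) ovi_stop("U_px must be at least 2", "validation_error")
  if (ground_mode == "fixed_row" && is.null(ground_row)) {
    ovi_stop("ground_row is required for fixed_row mode", "validation_error")
  }
  structure(list(withers_window = withers_window, hip_window = hip_window,
                 U_px = U_px, ground_mode = ground_mode, ground_row = ground_row,
                 cd_corner = match.arg(cd_corner)),
            class = "landmark_config")
}

default_chord_u <- function(S) max(5, round(0.05 * S))

#' Hip feature point in the raised-head posture
#'
#' The convex-hull vertex of the contour farthest toward the rear (the side
#' opposite the head) among vertices on the upper half of the silhouette
#' (`y` above the vertical midpoint of the contour bounds); ties go to the
#' highest point.
#'
#' @param contour a `contour` matrix.
#' @param head_side `"left"` or `"right"`.
#' @return numeric `(x, y)`.
#' @export
hip_point_headup <- function(contour, head_side = c("left", "right")) {
  head_side <- match.arg(head_side)
  hull <- convex_hull(contour)
  br <- bounding_rect(contour)
  ymid <- (br[["y0"]] + br[["y1"]]) / 2
  upper <- hull[hull[, 2] < ymid, , drop = FALSE]
  if (nrow(upper) == 0L) {
    ovi_stop("no convex-hull vertex on the upper half of the silhouette", "landmark_error")
  }
  rx <- if (head_side == "left") max(upper[, 1]) else min(upper[, 1])
  cand <- upper[upper[, 1] == rx, , drop = FALSE]
  as.numeric(cand[which.min(cand[, 2]), ])
}

snap_to_contour <- function(contour, p) {
  d2 <- (contour[, 1] - p[1])^2 + (contour[, 2] - p[2])^2
  which.min(d2)
}

#' Withers feature point in the raised-head posture
#'
#' Line A joins the top of the head to the shoulder point. Among the contour
#' points on the dorsal-side traversal arc between the two endpoints (the
#' arc not containing the lowest contour point), the point with maximal
#' perpendicular distance to line A is the withers. A perfectly straight
#' dorsal line yields the first arc point, flagged `"flat_dorsal"` (attribute
#' `flag`) with a warning.
#'
#' @param contour a `contour` matrix.
#' @param head_top top-of-head point (snapped to the contour).
#' @param shoulder shoulder point (snapped to the contour); callers usually
#'   take the head-side endpoint of the inscribed-rectangle top edge.
#' @return numeric `(x, y)`, possibly with attribute `flag`.
#' @export
withers_point_headup <- function(contour, head_top, shoulder) {
  if (all(as.numeric(head_top) == as.numeric(shoulder))) {
    ovi_stop("head_top and shoulder must be distinct", "validation_error")
  }
  n <- nrow(contour)
  ih <- snap_to_contour(contour, head_top)
  is_ <- snap_to_contour(contour, shoulder)
  if (ih == is_) ovi_stop("head_top and shoulder snap to the same contour point",
                          "validation_error")
  a <- contour[ih, ]; b <- contour[is_, ]
  arc_fwd <- if (ih <= is_) ih:is_ else c(ih:n, 1:is_)
  arc_bwd <- if (is_ <= ih) is_:ih else c(is_:n, 1:ih)
  ibottom <- which.max(contour[, 2])
  arc <- if (ibottom %in% arc_fwd[-c(1, length(arc_fwd))]) arc_bwd else arc_fwd
  inner <- arc[-c(1, length(arc))]
  if (length(inner) < 1L) {
    ovi_stop("dorsal arc between head and shoulder is too short", "landmark_error")
  }
  d <- vapply(inner, function(i) point_line_distance(contour[i, ], a, b), numeric(1))
  if (max(d) < 1e-6) {
    warning("dorsal line is straight; withers point is degenerate")
    out <- as.numeric(contour[inner[1], ])
    attr(out, "flag") <- "flat_dorsal"
    return(out)
  }
  as.numeric(contour[inner[which.max(d)], ])
}

upper_contour_indices <- function(contour) {
  # indices whose y equals the minimal contour y at their x column
  ymin <- tapply(contour[, 2], contour[, 1], min)
  keep <- contour[, 2] == as.numeric(ymin[as.character(contour[, 1])])
  which(keep)
}

#' Dorsal feature points in the lowered-head posture
#'
#' With the head lowered the scapula and hip bones protrude from the back
#' line. `S` is the horizontal extent of the contour; inside each fractional
#' window (measured from the head-side boundary), restricted to
#' upper-contour points, the point maximizing the convex-signed U-chord
#' curvature is taken.
#'
#' @param contour a `contour` matrix.
#' @param cfg a [landmark_config()].
#' @param head_side `"left"` or `"right"`.
#' @return list with `withers`, `hip` (each numeric `(x, y)`) and the
#'   curvature values attained.
#' @export
dorsal_points_headdown <- function(contour, cfg = landmark_config(),
                                   head_side = c("left", "right")) {
  head_side <- match.arg(head_side)
  xs <- contour[, 1]
  xmin <- min(xs); xmax <- max(xs)
  S <- xmax - xmin
  U <- cfg$U_px %||% default_chord_u(S)
  upper <- upper_contour_indices(contour)
  pick <- function(window) {
    if (head_side == "left") {
      lo <- xmin + window[1] * S; hi <- xmin + window[2] * S
    } else {
      lo <- xmax - window[2] * S; hi <- xmax - window[1] * S
    }
    cand <- upper[xs[upper] >= lo & xs[upper] <= hi]
    if (length(cand) == 0L) {
      ovi_stop("no upper-contour point inside the dorsal window", "landmark_error")
    }
    cs <- vapply(cand, function(i) u_chord_curvature(contour, i, U)$c, numeric(1))
    if (max(cs) <= 1e-9) {
      ovi_stop("dorsal window has no convex curvature maximum (flat back)", "landmark_error")
    }
    i <- cand[which.max(cs)]
    list(point = as.numeric(contour[i, ]), c = max(cs))
  }
  w <- pick(cfg$withers_window)
  h <- pick(cfg$hip_window)
  list(withers = w$point, hip = h$point,
       curvature = c(withers = w$c, hip = h$c), U = U)
}

#' Body-slant-length feature points
#'
#' The endpoints of the maximal inscribed rectangle's diagonal running from
#' the head-side lower corner to the rear upper corner (corner coordinates
#' at the half-open rectangle bounds). Either diagonal has the same length;
#' this one orients head-to-rear.
#'
#' @param mask a non-empty [binary_mask()].
#' @param head_side `"left"` or `"right"`.
#' @return list with `p1` (head-side lower corner), `p2` (rear upper
#'   corner), `length` in pixels and the `rect` itself.
#' @export
bsl_points <- function(mask, head_side = c("left", "right")) {
  head_side <- match.arg(head_side)
  r <- max_inscribed_rect(mask)
  p1 <- if (head_side == "left") c(r[["x0"]], r[["y1"]]) else c(r[["x1"]], r[["y1"]])
  p2 <- if (head_side == "left") c(r[["x1"]], r[["y0"]]) else c(r[["x0"]], r[["y0"]])
  list(p1 = p1, p2 = p2, length = pt_dist(p1, p2), rect = r)
}

#' Measure body-size traits on a classified silhouette
#'
#' Computes the four pixel measures. The ground line defaults to the bottom
#' of the lowest foreground row. Withers height and hip height are vertical
#' distances from the respective landmarks to the ground; body slanting
#' length is the inscribed-rectangle diagonal; chest depth is the straight
#' distance from the withers to the head-side lower corner of the inscribed
#' rectangle (a sternum proxy). Jump frames are not measured: the skeleton
#' is not in a measurable configuration mid-jump.
#'
#' @param mask a single-component [binary_mask()].
#' @param posture a `posture_result` from [classify_posture()], or a label
#'   string.
#' @param cfg a [landmark_config()].
#' @param head_side `"left"` or `"right"`.
#' @return a `measurement_record`: list with the pixel measures, the posture
#'   label and angle, a `landmarks` list and a `flags` string.
#' @export
measure <- function(mask, posture, cfg = landmark_config(),
                    head_side = c("left", "right")) {
  head_side <- match.arg(head_side)
  label <- if (inherits(posture, "posture_result")) posture$label else as.character(posture)
  angle <- if (inherits(posture, "posture_result")) posture$angle_deg else NA_real_
  if (label == "jump") {
    ovi_stop("body measures are not defined for the jump posture", "unsupported_posture_error")
  }
  if (!label %in% c("head_up", "head_down")) {
    ovi_stop(sprintf("unknown posture label '%s'", label), "validation_error")
  }
  contour <- extract_contour(mask)
  flags <- character(0)

  ground_y <- if (cfg$ground_mode == "fixed_row") {
    cfg$ground_row
  } else {
    max(which(apply(as_grid(mask), 1, any)))  # 1-based row of lowest fg = 0-based row + 1
  }

  bsl <- bsl_points(mask, head_side)

  if (label == "head_down") {
    dp <- dorsal_points_headdown(contour, cfg, head_side)
    withers <- dp$withers
    hip <- dp$hip
  } else {
    hip <- hip_point_headup(contour, head_side)
    r <- bsl$rect
    shoulder <- if (head_side == "left") c(r[["x0"]], r[["y0"]]) else c(r[["x1"]], r[["y0"]])
    ahead <- if (head_side == "left") contour[, 1] < shoulder[1] else contour[, 1] > shoulder[1]
    head_top <- if (any(ahead)) {
      cand <- contour[ahead, , drop = FALSE]
      as.numeric(cand[which.min(cand[, 2]), ])
    } else {
      head_point(contour, head_side)
    }
    ish <- snap_to_contour(contour, shoulder)
    shoulder_c <- as.numeric(contour[ish, ])
    if (all(head_top == shoulder_c)) {
      withers <- shoulder_c
      flags <- c(flags, "degenerate_line_a")
    } else {
      withers <- withers_point_headup(contour, head_top, shoulder_c)
      if (!is.null(attr(withers, "flag"))) flags <- c(flags, attr(withers, "flag"))
      attributes(withers) <- NULL
    }
  }

  if (ground_y < withers[2] || ground_y < hip[2]) {
    flags <- c(flags, "landmark_below_ground")
  }
  cd_end <- if (cfg$cd_corner == "lower") bsl$p1 else bsl$p2
  rec <- structure(list(
    posture = label,
    angle_deg = angle,
    bsl_px = bsl$length,
    wh_px = ground_y - withers[2],
    hh_px = ground_y - hip[2],
    cd_px = pt_dist(withers, cd_end),
    bsl_cm = NA_real_, wh_cm = NA_real_, hh_cm = NA_real_, cd_cm = NA_real_,
    flags = paste(flags, collapse = ";"),
    landmarks = list(withers = withers, hip = hip,
                     bsl_p1 = bsl$p1, bsl_p2 = bsl$p2,
                     head = head_point(contour, head_side),
                     ground_y = ground_y)
  ), class = "measurement_record")
  rec
}

#' Convert the pixel measures of a record to centimeters
#'
#' @param record a `measurement_record` from [measure()].
#' @param ratio pixels-per-centimeter scale (see [eval_ratio()]).
#' @return the record with `*_cm` fields filled.
#' @export
apply_calibration <- function(record, ratio) {
  record$bsl_cm <- px_to_cm(record$bsl_px, ratio)
  record$wh_cm <- px_to_cm(record$wh_px, ratio)
  record$hh_cm <- px_to_cm(record$hh_px, ratio)
  record$cd_cm <- px_to_cm(record$cd_px, ratio)
  record
}

#' One-row data frame view of a measurement record
#'
#' @param x a `measurement_record`.
#' @param ear_tag,frame identifiers for the output row.
#' @param ... unused.
#' @return a one-row data frame with the 13 standard columns.
#' @export
as.data.frame.measurement_record <- function(x, ear_tag = NA_character_,
                                             frame = NA_integer_, ...) {
  data.frame(ear_tag = as.character(ear_tag), frame = frame,
             posture = x$posture, angle_deg = x$angle_deg,
             bsl_px = x$bsl_px, wh_px = x$wh_px, hh_px = x$hh_px, cd_px = x$cd_px,
             bsl_cm = x$bsl_cm, wh_cm = x$wh_cm, hh_cm = x$hh_cm, cd_cm = x$cd_cm,
             flags = x$flags, stringsAsFactors = FALSE)
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("<measurement_record %s: BSL %.1f, WH %.1f, HH %.1f, CD %.1f px>\n",
              x$posture, x$bsl_px, x$wh_px, x$hh_px, x$cd_px))
  invisible(x)
}
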