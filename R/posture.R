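# Posture recognition: jumping animals show a whole-body rotation that opens
# an angle between the diagonals of the two enclosing rectangles; the
# remaining frames split into head-up vs head-down by comparing the head
# point's height with the hip point's.

#' Posture classifier configuration
#'
#' @param jump_angle_threshold_deg decision-stump threshold on the
#'   rectangle-angle statistic; frames above it are jumps. The default 8.9
#'   degrees is the decision-tree split fitted on channel recordings.
#' @param angle_mode `"diagonal"` (angle between the min-area-rectangle
#'   diagonal and the bounding-rectangle diagonal) or `"axis"` (absolute
#'   long-axis orientation of the min-area rectangle).
#' @param head_side which image side the head faces, `"left"` or `"right"`.
#' @return a `posture_config`.
#' @export
posture_config <- function(jump_angle_threshold_deg = 8.9,
                           angle_mode = c("diagonal", "axis"),
                           head_side = c("left", "right")) {
  if (jump_angle_threshold_deg <= 0) ovi_stop("threshold must be positive", "validation_error")
  structure(list(jump_angle_threshold_deg = jump_angle_threshold_deg,
                 angle_mode = match.arg(angle_mode),
                 head_side = match.arg(head_side)),
            class = "posture_config")
}

#' Rectangle-angle posture statistic
#'
#' In `diagonal` mode: the acute angle between (a) the diagonal of the
#' minimum-area rectangle joining its corner of minimal `x + y` to the corner
#' of maximal `x + y` and (b) the identically-defined diagonal of the
#' axis-aligned bounding rectangle. In `axis` mode: the absolute orientation
#' of the minimum-area rectangle's long axis. A level walking animal scores
#' near 0 in both modes; a rotated (jumping) body opens the angle.
#'
#' @param contour a `contour` matrix.
#' @param mode `"diagonal"` or `"axis"`.
#' @return angle in degrees, in `[0, 90]`.
#' @export
posture_angle <- function(contour, mode = c("diagonal", "axis")) {
  mode <- match.arg(mode)
  mar <- min_area_rect(contour)
  if (mode == "axis") return(abs(mar$angle_deg))
  corners <- rect_corners(mar)
  sums <- corners[, 1] + corners[, 2]
  v1 <- corners[which.max(sums), ] - corners[which.min(sums), ]
  # tight point extents, so a level rectangle scores exactly zero
  v2 <- c(diff(range(contour[, 1])), diff(range(contour[, 2])))
  cosang <- abs(sum(v1 * v2)) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  unname(acos(min(1, max(-1, cosang))) * 180 / pi)
}

#' Head point of a silhouette contour
#'
#' The extreme point on the configured head side (minimal x for
#' `head_side = "left"`, maximal x otherwise); ties go to the highest
#' (smallest y) point.
#'
#' @param contour a `contour` matrix.
#' @param head_side `"left"` or `"right"`.
#' @return numeric `(x, y)`.
#' @export
head_point <- function(contour, head_side = c("left", "right")) {
  head_side <- match.arg(head_side)
  xs <- contour[, 1]
  xm <- if (head_side == "left") min(xs) else max(xs)
  cand <- contour[xs == xm, , drop = FALSE]
  as.numeric(cand[which.min(cand[, 2]), ])
}

#' Classify the walking posture of a silhouette
#'
#' Decision order: (1) rectangle-angle statistic above the jump threshold
#' gives `jump`; (2) otherwise a head point strictly higher in the image
#' than the hip point gives `head_up`; (3) otherwise `head_down` (a head
#' exactly level with the hip counts as down, the majority posture).
#'
#' The statistic is computed in a canonical head-left orientation:
#' `head_side = "right"` inputs are mirrored first, which makes the result
#' exactly mirror-symmetric (the diagonal construction alone is not).
#'
#' @param mask a [binary_mask()] with a single connected component.
#' @param cfg a [posture_config()].
#' @return a `posture_result`: list with `label`, `angle_deg`, `head_point`,
#'   `hip_point`.
#' @export
classify_posture <- function(mask, cfg = posture_config()) {
  w <- mask_width(mask)
  flip <- cfg$head_side == "right"
  canon <- if (flip) binary_mask(as_grid(mask)[, w:1, drop = FALSE]) else mask
  contour <- extract_contour(canon)
  angle <- posture_angle(contour, cfg$angle_mode)
  head <- head_point(contour, "left")
  hip <- hip_point_headup(contour, "left")
  if (flip) {
    head[1] <- w - 1 - head[1]
    hip[1] <- w - 1 - hip[1]
  }
  label <- if (angle > cfg$jump_angle_threshold_deg) {
    "jump"
  } else if (head[2] < hip[2]) {
    "head_up"
  } else {
    "head_down"
  }
  structure(list(label = label, angle_deg = angle,
                 head_point = head, hip_point = hip),
            class = "posture_result")
}

#' @export
print.posture_result <- function(x, ...) {
  cat(sprintf("<posture_result %s, angle %.2f deg>\n", x$label, x$angle_deg))
  invisible(x)
}

#' Fit a one-threshold jump classifier
#'
#' Exhaustive decision-stump search over midpoints between consecutive
#' sorted angle values, predicting `jump` for angles strictly above the
#' threshold. The training-accuracy-maximizing threshold is returned; ties
#' go to the smallest threshold.
#'
#' @param angles numeric rectangle-angle statistics.
#' @param is_jump logical (or coercible) jump labels; both classes must be
#'   present.
#' @return list with `threshold` and training `accuracy`.
#' @export
fit_jump_stump <- function(angles, is_jump) {
  is_jump <- as.logical(is_jump)
  if (length(angles) != length(is_jump) || anyNA(angles) || anyNA(is_jump)) {
    ovi_stop("angles and labels must align and be complete", "validation_error")
  }
  if (length(unique(is_jump)) < 2L) {
    ovi_stop("both classes must be present to fit a stump", "validation_error")
  }
  u <- sort(unique(angles))
  cand <- (u[-length(u)] + u[-1]) / 2
  acc <- vapply(cand, function(t) mean((angles > t) == is_jump), numeric(1))
  best <- which(acc == max(acc))[1]  # candidates ascending: smallest threshold wins ties
  list(threshold = cand[best], accuracy = acc[best])
}
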