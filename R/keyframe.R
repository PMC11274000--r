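# Key-frame screening: score every frame of a channel pass by a weighted
# count of mask pixels in three nested, centered regions, and keep the frame
# where the animal is most fully and centrally visible.

#' Region weights for key-frame scoring
#'
#' Three nested fractional regions of the frame and their weights. The
#' defaults put region 1 at `x in [1/3, 2/3)`, `y in [0.375, 0.625)`,
#' region 2 at `x in [1/6, 5/6)`, `y in [1/4, 3/4)`, and region 3 at the
#' full frame, with weights 10, 0.5 and 0.01: a pixel near the frame center
#' is worth three orders of magnitude more than one at the border.
#'
#' @param n1,n2,n3 positive region weights.
#' @param r1,r2,r3 fractional bounds `c(xlo, xhi, ylo, yhi)` in `[0, 1]`,
#'   half-open; regions must nest `r1 <= r2 <= r3`.
#' @return a `region_weights` object.
#' @export
region_weights <- function(n1 = 10, n2 = 0.5, n3 = 0.01,
                           r1 = c(1/3, 2/3, 0.375, 0.625),
                           r2 = c(1/6, 5/6, 0.25, 0.75),
                           r3 = c(0, 1, 0, 1)) {
  w <- c(n1, n2, n3)
  if (any(!is.finite(w)) || any(w <= 0)) ovi_stop("weights must be positive", "validation_error")
  for (r in list(r1, r2, r3)) {
    if (length(r) != 4L || any(r < 0) || any(r > 1) || r[1] >= r[2] || r[3] >= r[4]) {
      ovi_stop("region bounds must be c(xlo, xhi, ylo, yhi) within [0, 1]", "validation_error")
    }
  }
  nested <- r1[1] >= r2[1] && r1[2] <= r2[2] && r1[3] >= r2[3] && r1[4] <= r2[4] &&
            r2[1] >= r3[1] && r2[2] <= r3[2] && r2[3] >= r3[3] && r2[4] <= r3[4]
  if (!nested) ovi_stop("regions must nest: r1 within r2 within r3", "validation_error")
  structure(list(n = w, regions = list(r1, r2, r3)), class = "region_weights")
}

#' Count mask pixels inside a fractional region
#'
#' Fractional bounds are converted to half-open pixel bounds with
#' `floor(lo * dim) <= coord < floor(hi * dim)` on each axis.
#'
#' @param mask a [binary_mask()].
#' @param region_frac fractional bounds `c(xlo, xhi, ylo, yhi)`.
#' @return integer count of foreground pixels in the region.
#' @export
region_pixel_count <- function(mask, region_frac) {
  w <- mask_width(mask); h <- mask_height(mask)
  x0 <- floor(region_frac[1] * w); x1 <- floor(region_frac[2] * w)
  y0 <- floor(region_frac[3] * h); y1 <- floor(region_frac[4] * h)
  if (x1 <= x0 || y1 <= y0) return(0L)
  sum(as_grid(mask)[(y0 + 1):y1, (x0 + 1):x1])
}

#' Weighted-region frame score
#'
#' `score = n1 * |R1| + n2 * |R2| + n3 * |R3|` where `|Ri|` is the mask pixel
#' count in region i. The regions nest, so with the default (`nested`)
#' counting a centered pixel contributes to all three terms; `exclusive`
#' counting scores each pixel only in the innermost annulus it falls in.
#'
#' @param mask a [binary_mask()].
#' @param w a [region_weights()].
#' @param counting `"nested"` (default) or `"exclusive"`.
#' @return numeric score.
#' @export
frame_score <- function(mask, w = region_weights(), counting = c("nested", "exclusive")) {
  counting <- match.arg(counting)
  cnt <- vapply(w$regions, function(r) as.numeric(region_pixel_count(mask, r)), numeric(1))
  if (counting == "exclusive") cnt <- c(cnt[1], cnt[2] - cnt[1], cnt[3] - cnt[2])
  sum(w$n * cnt)
}

#' Select the key frame of a channel pass
#'
#' The frame with the maximal [frame_score()]; ties go to the smallest
#' frame index.
#'
#' @param seq a [frame_sequence()].
#' @param w a [region_weights()].
#' @param counting see [frame_score()].
#' @return list with `frame_index`, `score`, and the full `scores` vector
#'   (named by frame index).
#' @export
select_key_frame <- function(seq, w = region_weights(), counting = "nested") {
  if (!inherits(seq, "frame_sequence") || length(seq$frames) == 0L) {
    ovi_stop("need a non-empty frame sequence", "validation_error")
  }
  scores <- vapply(seq$frames, function(f) frame_score(f$mask, w, counting), numeric(1))
  idx <- vapply(seq$frames, function(f) as.numeric(f$index), numeric(1))
  best <- which.max(scores)  # first maximum; frames are ordered by index
  list(frame_index = idx[best], score = scores[best],
       scores = stats::setNames(scores, idx))
}
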