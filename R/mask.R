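#' Binary silhouette mask
#'
#' A `binary_mask` is a logical matrix with `height` rows and `width` columns.
#' Pixel `(x, y)` (0-based, x right, y down) is stored at `grid[y + 1, x + 1]`.
#'
#' @param grid logical (or coercible numeric) matrix; `NA` is treated as
#'   background.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(grid) {
  if (!is.matrix(grid)) ovi_stop("mask grid must be a matrix", "validation_error")
  if (!is.logical(grid)) {
    grid <- matrix(as.logical(grid != 0), nrow(grid), ncol(grid))
  }
  if (nrow(grid) < 1L || ncol(grid) < 1L) {
    ovi_stop("mask must have positive width and height", "validation_error")
  }
  grid[is.na(grid)] <- FALSE
  structure(grid, class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d foreground>\n",
              mask_width(x), mask_height(x), mask_area(x)))
  invisible(x)
}

#' Mask dimensions and foreground area
#' @param mask a [binary_mask()].
#' @return integer width, height or foreground pixel count.
#' @export
mask_width <- function(mask) ncol(mask)

#' @rdname mask_width
#' @export
mask_height <- function(mask) nrow(mask)

#' @rdname mask_width
#' @export
mask_area <- function(mask) sum(mask)

as_grid <- function(mask) {
  # plain logical matrix, stripped of the S3 class
  matrix(as.logical(mask), nrow(mask), ncol(mask))
}

#' Read a mask image and binarize it
#'
#' Reads an 8-bit gray or RGB(A) PNG and thresholds it: a pixel is foreground
#' iff its gray level (luma for RGB) is at least `threshold` on the 0-255
#' scale. Segmentation masks are 0/255 in practice, so the default of 128 is
#' insensitive to interpolation artifacts.
#'
#' @param path PNG file path.
#' @param threshold gray level in `[1, 255]`; default 128.
#' @return a [binary_mask()].
#' @export
load_mask <- function(path, threshold = 128) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 1 || threshold > 255) {
    ovi_stop("threshold must be a single gray level in [1, 255]", "validation_error")
  }
  img <- tryCatch(png::readPNG(path),
                  error = function(e) ovi_stop(
                    sprintf("cannot read PNG '%s': %s", path, conditionMessage(e)),
                    "io_error"))
  gray <- if (length(dim(img)) == 2L) {
    img
  } else if (dim(img)[3] == 2L) {      # gray + alpha
    img[, , 1L]
  } else {                              # RGB(A): ITU-R BT.601 luma
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  }
  if (length(gray) == 0L) ovi_stop("zero-area image", "validation_error")
  binary_mask(gray * 255 >= threshold - 1e-7)
}

#' Write a mask as an 8-bit PNG (0/255)
#' @param mask a [binary_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  ok <- tryCatch({ png::writePNG(as_grid(mask) * 1, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) ovi_stop(sprintf("cannot write PNG '%s'", path), "io_error")
  invisible(path)
}

#' Rasterize polygon annotations into a mask
#'
#' A pixel is foreground iff its center `(x + 0.5, y + 0.5)` lies inside any
#' polygon under the even-odd rule; overlapping polygons union.
#'
#' @param polygons list of polygons, each an `n x 2` matrix of `(x, y)`
#'   vertices (n >= 3 distinct vertices).
#' @param width,height output raster size in pixels.
#' @return a [binary_mask()].
#' @export
rasterize_polygons <- function(polygons, width, height) {
  if (width < 1 || height < 1) ovi_stop("raster must be at least 1 x 1", "validation_error")
  out <- matrix(FALSE, height, width)
  cx <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  cy <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  for (poly in polygons) {
    poly <- as.matrix(poly)
    if (ncol(poly) != 2L) ovi_stop("polygon must be an n x 2 matrix", "validation_error")
    if (nrow(unique(poly)) < 3L) {
      ovi_stop("degenerate polygon: fewer than 3 distinct vertices", "validation_error")
    }
    inside <- matrix(FALSE, height, width)
    n <- nrow(poly)
    xs <- poly[, 1]; ys <- poly[, 2]
    j <- n
    for (i in seq_len(n)) {
      yi <- ys[i]; yj <- ys[j]
      if (yi != yj) {
        crosses <- (yi > cy) != (yj > cy)
        xint <- xs[i] + (cy - yi) * (xs[j] - xs[i]) / (yj - yi)
        inside <- xor(inside, crosses & (cx < xint))
      }
      j <- i
    }
    out <- out | inside
  }
  binary_mask(out)
}

#' Read a polygon-annotation JSON file
#'
#' Consumes the labeling-tool dialect with fields `shapes[].points`,
#' `imageWidth` and `imageHeight`.
#'
#' @param path JSON file path.
#' @return list with `polygons` (list of n x 2 matrices), `width`, `height`.
#' @export
read_polygon_annotation <- function(path) {
  ann <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) ovi_stop(
                    sprintf("cannot parse annotation '%s'", path), "io_error"))
  if (is.null(ann$imageWidth) || is.null(ann$imageHeight)) {
    ovi_stop("annotation lacks imageWidth/imageHeight", "validation_error")
  }
  polys <- lapply(ann$shapes, function(sh) {
    do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
  })
  list(polygons = polys,
       width = as.integer(ann$imageWidth),
       height = as.integer(ann$imageHeight))
}

# --- connected components (8-connectivity) ---------------------------------

# EBImage::bwlabel labels 4-connected sets; merge labels that touch
# diagonally to obtain 8-connected components.
label_components8 <- function(mask) {
  g <- as_grid(mask)
  lab <- EBImage::bwlabel(g * 1)
  lab <- matrix(as.integer(lab), nrow(g), ncol(g))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  se_a <- lab[-nr, -nc]; se_b <- lab[-1, -1]    # (r,c) ~ (r+1,c+1)
  sw_a <- lab[-nr, -1];  sw_b <- lab[-1, -nc]   # (r,c) ~ (r+1,c-1)
  pairs <- rbind(
    cbind(as.vector(se_a), as.vector(se_b)),
    cbind(as.vector(sw_a), as.vector(sw_b))
  )
  pairs <- unique(pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Keep only the largest 8-connected component
#'
#' Ties in pixel count are broken by the component containing the first
#' foreground pixel in row-major order (top-left-most).
#'
#' @param mask a [binary_mask()].
#' @return a [binary_mask()] with a single component.
#' @export
largest_component <- function(mask) {
  if (!any(mask)) ovi_stop("mask is empty", "empty_mask_error")
  lab <- label_components8(mask)
  nlab <- max(lab)
  if (nlab == 1L) return(binary_mask(lab == 1L))
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  # row-major key of the first pixel of each component
  w <- ncol(lab)
  rows <- row(lab) - 1L; cols <- col(lab) - 1L
  key <- rows * w + cols
  first_key <- vapply(seq_len(nlab), function(k) min(key[lab == k]), numeric(1))
  best <- order(-sizes, first_key)[1]
  binary_mask(lab == best)
}

#' Number of 8-connected components
#' @param mask a [binary_mask()].
#' @return integer count.
#' @export
n_components <- function(mask) {
  if (!any(mask)) return(0L)
  max(label_components8(mask))
}

# --- contour tracing ---------------------------------------------------------

#' Trace the boundary contour of a single-component mask
#'
#' Moore-neighbor tracing, clockwise when viewed with y growing downward
#' (the interior stays on the walker's right). The traversal starts at the
#' top-left-most foreground pixel and closes implicitly. One-pixel-wide
#' structures are traversed down and back, so a pixel may appear twice in the
#' sequence (never consecutively).
#'
#' @param mask a [binary_mask()] with exactly one 8-connected component.
#' @return a `contour`: an `n x 2` matrix of 0-based `(x, y)` pixel
#'   coordinates, n >= 3.
#' @export
extract_contour <- function(mask) {
  if (!any(mask)) ovi_stop("mask is empty", "empty_mask_error")
  if (n_components(mask) != 1L) {
    ovi_stop("mask has more than one connected component", "validation_error")
  }
  g <- as_grid(mask)
  h <- nrow(g); w <- ncol(g)
  fg <- function(x, y) x >= 0L && x < w && y >= 0L && y < h && g[y + 1L, x + 1L]
  # first foreground pixel in row-major order
  tg <- t(g)
  i0 <- which(tg)[1]
  sy <- (i0 - 1L) %/% w
  sx <- (i0 - 1L) %% w
  # clockwise neighbor order (y down): E SE S SW W NW N NE
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  pts <- matrix(NA_integer_, 4L * sum(g) + 8L, 2L)
  pts[1L, ] <- c(sx, sy)
  np <- 1L
  cx <- sx; cy <- sy
  back <- 5L  # W: background, since (sx, sy) is first in its row segment
  d_first <- NA_integer_
  moved <- FALSE
  repeat {
    # next move: scan the Moore neighborhood clockwise starting after backtrack
    nxt <- 0L
    for (k in seq_len(8L)) {
      d <- (back + k - 1L) %% 8L + 1L
      if (fg(cx + dx[d], cy + dy[d])) { nxt <- d; break }
    }
    if (nxt == 0L) break  # isolated pixel: no neighbors
    # Jacob's criterion: stop when leaving the start in the initial direction
    if (moved && cx == sx && cy == sy && nxt == d_first) break
    if (!moved) { d_first <- nxt; moved <- TRUE }
    prev <- (nxt + 6L) %% 8L + 1L    # last background neighbor scanned
    bx <- cx + dx[prev]; by <- cy + dy[prev]
    cx <- cx + dx[nxt]; cy <- cy + dy[nxt]
    back <- which(dx == (bx - cx) & dy == (by - cy))
    np <- np + 1L
    if (np > nrow(pts)) ovi_stop("contour tracing failed to terminate", "validation_error")
    pts[np, ] <- c(cx, cy)
  }
  # drop the implicit closing copy of the start point
  if (np > 1L && pts[np, 1L] == pts[1L, 1L] && pts[np, 2L] == pts[1L, 2L]) np <- np - 1L
  pts <- pts[seq_len(np), , drop = FALSE]
  if (nrow(pts) < 3L) {
    ovi_stop("contour needs at least 3 points (component too small)", "validation_error")
  }
  colnames(pts) <- c("x", "y")
  structure(pts, class = c("contour", "matrix"))
}

# --- frame sequences ---------------------------------------------------------

#' Ordered per-animal frame sequence
#'
#' @param animal_id ear-tag identifier.
#' @param view `"side"` or `"back"`.
#' @param frames list of `list(index =, mask =)` entries; indices must be
#'   strictly increasing and all masks share one resolution.
#' @return a `frame_sequence`.
#' @export
frame_sequence <- function(animal_id, view = c("side", "back"), frames) {
  view <- match.arg(view)
  if (length(frames) == 0L) ovi_stop("frame sequence is empty", "validation_error")
  idx <- vapply(frames, function(f) as.numeric(f$index), numeric(1))
  if (any(diff(idx) <= 0)) {
    ovi_stop("frame indices must be strictly increasing", "validation_error")
  }
  dims <- vapply(frames, function(f) dim(f$mask), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ovi_stop("all frames must share one resolution", "validation_error")
  }
  structure(list(animal_id = as.character(animal_id), view = view, frames = frames),
            class = "frame_sequence")
}

#' Read a per-animal frame folder
#'
#' Expects the layout `<root>/<ear_tag>/<view>/<frame_index>.png`.
#'
#' @param root dataset root directory.
#' @param ear_tag animal folder name.
#' @param view `"side"` or `"back"`.
#' @param threshold binarization gray level, see [load_mask()].
#' @return a [frame_sequence()].
#' @export
read_frame_folder <- function(root, ear_tag, view = "side", threshold = 128) {
  dir <- file.path(root, ear_tag, view)
  files <- list.files(dir, pattern = "^[0-9]+\\.png$", full.names = TRUE)
  if (length(files) == 0L) {
    ovi_stop(sprintf("no frames under '%s'", dir), "io_error")
  }
  idx <- as.integer(sub("\\.png$", "", basename(files)))
  ord <- order(idx)
  frames <- lapply(ord, function(i) list(index = idx[i], mask = load_mask(files[i], threshold)))
  frame_sequence(ear_tag, view, frames)
}

# --- measurement CSV ---------------------------------------------------------

measurement_columns <- c("ear_tag", "frame", "posture", "angle_deg",
                         "bsl_px", "wh_px", "hh_px", "cd_px",
                         "bsl_cm", "wh_cm", "hh_cm", "cd_cm", "flags")

#' Write measurement records to CSV
#'
#' One row per animal/frame with the standard 13 columns; numeric values are
#' rendered with two decimals so reruns are byte-identical.
#'
#' @param records a data frame of measurement rows (see
#'   [as.data.frame.measurement_record()]) or a list of such rows.
#' @param path output CSV path.
#' @export
write_measurements <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(measurement_columns)),
                                      measurement_columns))
  }
  missing <- setdiff(measurement_columns, names(records))
  for (m in missing) records[[m]] <- NA
  records <- records[, measurement_columns, drop = FALSE]
  num_cols <- c("angle_deg", "bsl_px", "wh_px", "hh_px", "cd_px",
                "bsl_cm", "wh_cm", "hh_cm", "cd_cm")
  out <- records
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(records[[cc]]))
    out[[cc]] <- ifelse(is.na(v), "", sprintf("%.2f", v))
  }
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(measurement_columns, collapse = ","), con)
    if (nrow(out) > 0L) {
      apply(out, 1L, function(r) writeLines(paste(r, collapse = ","), con))
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ovi_stop(sprintf("cannot write '%s'", path), "io_error")
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#' @param path CSV path.
#' @return data frame with the standard columns.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ear_tag = "character", flags = "character"))
  df
}
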