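# End-to-end orchestration over a dataset tree, plus the evaluation metrics
# used to report classification quality. Per-animal failures are logged and
# skipped; a messy channel recording must never abort a whole run.

#' Confusion counts for one positive class
#'
#' @param pred,truth equal-length label vectors.
#' @param positive the class treated as positive.
#' @return list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth, positive) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    ovi_stop("pred and truth must be non-empty and aligned", "validation_error")
  }
  p <- pred == positive; t <- truth == positive
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Precision and recall
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.
#'
#' @param counts a list with `TP`, `FP`, `FN` (e.g. from
#'   [confusion_counts()]).
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(counts) {
  if (counts$TP + counts$FP == 0) {
    ovi_stop("precision undefined: no positive predictions", "metric_error")
  }
  counts$TP / (counts$TP + counts$FP)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  if (counts$TP + counts$FN == 0) {
    ovi_stop("recall undefined: no positive truths", "metric_error")
  }
  counts$TP / (counts$TP + counts$FN)
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Stratified accuracy report
#'
#' Per-group correct counts and accuracy percentages (rounded half-up to two
#' decimals), with an overall `Total` row.
#'
#' @param pred,truth equal-length label vectors.
#' @param groups optional stratifier (e.g. sex x posture), same length.
#' @return data frame with columns `group`, `n`, `correct`, `accuracy_pct`.
#' @export
accuracy_report <- function(pred, truth, groups = NULL) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    ovi_stop("pred and truth must be non-empty and aligned", "validation_error")
  }
  ok <- pred == truth
  if (is.null(groups)) groups <- rep("all", length(pred))
  n <- tapply(ok, groups, length)
  correct <- tapply(ok, groups, sum)
  accuracy_table(as.integer(correct), as.integer(n), names(n))
}

#' Accuracy table from per-stratum counts
#'
#' @param correct,n integer vectors of correctly-identified and total counts
#'   per stratum.
#' @param groups stratum labels.
#' @return data frame with per-stratum rows and a `Total` row;
#'   `accuracy_pct` is rounded half-up to two decimals.
#' @export
accuracy_table <- function(correct, n, groups = seq_along(n)) {
  if (length(correct) != length(n) || any(correct > n) || any(n <= 0)) {
    ovi_stop("need correct <= n with positive n per stratum", "validation_error")
  }
  df <- data.frame(group = as.character(groups), n = n, correct = correct,
                   accuracy_pct = round_half_up(100 * correct / n),
                   stringsAsFactors = FALSE)
  total <- data.frame(group = "Total", n = sum(n), correct = sum(correct),
                      accuracy_pct = round_half_up(100 * sum(correct) / sum(n)),
                      stringsAsFactors = FALSE)
  rbind(df, total)
}

#' Pipeline configuration
#'
#' @param weights a [region_weights()].
#' @param posture a [posture_config()].
#' @param landmarks a [landmark_config()].
#' @param calibration optional [calibration_model()] for cm conversion.
#' @param cal_u,cal_v per-run predictor values (cm) at which the calibration
#'   model is evaluated (e.g. sheep-to-backplane and camera-to-backplane
#'   distances for the side camera).
#' @param view which camera view to process.
#' @param threshold mask binarization gray level.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(weights = region_weights(),
                            posture = posture_config(),
                            landmarks = landmark_config(),
                            calibration = NULL, cal_u = NULL, cal_v = NULL,
                            view = "side", threshold = 128) {
  if (!is.null(calibration) && (is.null(cal_u) || is.null(cal_v))) {
    ovi_stop("cm conversion needs cal_u and cal_v alongside the model", "validation_error")
  }
  structure(list(weights = weights, posture = posture, landmarks = landmarks,
                 calibration = calibration, cal_u = cal_u, cal_v = cal_v,
                 view = view, threshold = threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `weights` (n1, n2, n3), `posture`
#' (jump_angle_threshold_deg, angle_mode, head_side), `landmarks` (U_px,
#' ground_mode, ground_row, cd_corner), `calibration` (preset name or model
#' file path), `cal_u`, `cal_v`, `view`, `threshold`. Missing keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  w <- do.call(region_weights, y$weights %||% list())
  po <- do.call(posture_config, y$posture %||% list())
  lm_args <- y$landmarks %||% list()
  lmk <- do.call(landmark_config, lm_args)
  calib <- NULL
  if (!is.null(y$calibration)) {
    calib <- if (file.exists(y$calibration)) read_calibration(y$calibration)
             else calibration_preset(y$calibration)
  }
  pipeline_config(weights = w, posture = po, landmarks = lmk,
                  calibration = calib, cal_u = y$cal_u, cal_v = y$cal_v,
                  view = y$view %||% "side", threshold = y$threshold %||% 128)
}

#' Run the full measurement pipeline over a dataset tree
#'
#' For every animal folder under `root`: load its frame masks, select the
#' key frame, classify posture, and measure the non-jump frames (jump
#' frames are emitted with blank measures and flag `jump_excluded`).
#' Multi-component masks are reduced to their largest component with a
#' logged warning. Per-animal failures are logged and the run continues.
#'
#' @param root dataset root with layout `<root>/<ear_tag>/<view>/<idx>.png`.
#' @param cfg a [pipeline_config()].
#' @param output_csv optional path for the measurement CSV.
#' @return a `pipeline_run`: list with `measurements` (data frame),
#'   `failures` (data frame of ear_tag/error), and `log` (character).
#' @export
run_pipeline <- function(root, cfg = pipeline_config(), output_csv = NULL) {
  animals <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(animals) == 0L) ovi_stop(sprintf("no animal folders under '%s'", root),
                                      "validation_error")
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  rows <- list(); fails <- list()
  for (tag in animals) {
    res <- tryCatch({
      seq <- read_frame_folder(root, tag, cfg$view, cfg$threshold)
      seq$frames <- lapply(seq$frames, function(f) {
        nc <- n_components(f$mask)
        if (nc > 1L) {
          say("[%s] frame %d: %d components, keeping largest", tag, f$index, nc)
          f$mask <- largest_component(f$mask)
        }
        f
      })
      kf <- select_key_frame(seq, cfg$weights)
      mask <- seq$frames[[which(vapply(seq$frames, `[[`, numeric(1), "index") == kf$frame_index)]]$mask
      pr <- classify_posture(mask, cfg$posture)
      say("[%s] key frame %d, posture %s (angle %.2f)",
          tag, kf$frame_index, pr$label, pr$angle_deg)
      if (pr$label == "jump") {
        data.frame(ear_tag = tag, frame = kf$frame_index, posture = "jump",
                   angle_deg = pr$angle_deg,
                   bsl_px = NA_real_, wh_px = NA_real_, hh_px = NA_real_, cd_px = NA_real_,
                   bsl_cm = NA_real_, wh_cm = NA_real_, hh_cm = NA_real_, cd_cm = NA_real_,
                   flags = "jump_excluded", stringsAsFactors = FALSE)
      } else {
        rec <- measure(mask, pr, cfg$landmarks, cfg$posture$head_side)
        if (!is.null(cfg$calibration)) {
          ratio <- eval_ratio(cfg$calibration, cfg$cal_u, cfg$cal_v)
          rec <- apply_calibration(rec, ratio)
        }
        as.data.frame(rec, ear_tag = tag, frame = kf$frame_index)
      }
    }, error = function(e) {
      say("[%s] FAILED: %s", tag, conditionMessage(e))
      structure(list(ear_tag = tag, error = conditionMessage(e)), class = "ovi_fail")
    })
    if (inherits(res, "ovi_fail")) fails[[tag]] <- res else rows[[tag]] <- res
  }
  measurements <- if (length(rows)) do.call(rbind, unname(rows)) else
    as.data.frame(setNames(rep(list(character(0)), length(measurement_columns)),
                           measurement_columns))
  failures <- if (length(fails)) {
    data.frame(ear_tag = vapply(fails, `[[`, "", "ear_tag"),
               error = vapply(fails, `[[`, "", "error"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(ear_tag = character(0), error = character(0))
  say("done: %d measured, %d failed", nrow(measurements), nrow(failures))
  if (!is.null(output_csv)) write_measurements(measurements, output_csv)
  structure(list(measurements = measurements, failures = failures, log = log),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d animals measured, %d failed>\n",
              nrow(x$measurements), nrow(x$failures)))
  invisible(x)
}

#' Write a synthetic dataset tree to disk
#'
#' Renders silhouettes for the given parameter list as mask PNGs in the
#' standard folder layout, one walk sequence per animal.
#'
#' @param dir output root directory.
#' @param param_list named list: ear tag -> [silhouette_params()].
#' @param n_frames frames per pass.
#' @param seed base seed; animal `k` uses `seed + k`.
#' @return invisibly, a data frame of animal truth labels.
#' @export
write_synthetic_tree <- function(dir, param_list, n_frames = 5, seed = 1) {
  truth <- list()
  for (k in seq_along(param_list)) {
    tag <- names(param_list)[k]
    seq <- make_walk_sequence(param_list[[k]], n_frames, seed + k)
    sub <- file.path(dir, tag, "side")
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    for (f in seq$frames) {
      write_mask(f$mask, file.path(sub, sprintf("%d.png", f$index)))
    }
    truth[[tag]] <- data.frame(ear_tag = tag,
                               posture = attr(seq, "truth")$base$posture,
                               stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, unname(truth)))
}
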