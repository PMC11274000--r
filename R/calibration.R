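# Pixel-to-centimeter conversion. The camera's scale (pixels per
# centimeter) varies with the distance between animal and backplane and with
# the camera geometry; it is modelled as an additive cubic polynomial in two
# distance predictors, fitted to calibration-plate observations taken at
# 5-cm steps.

#' Calibration ratio model
#'
#' `ratio(u, v) = intercept + a1 u + a2 u^2 + a3 u^3 + b1 v + b2 v^2 + b3 v^3`
#' in pixels per centimeter. For the side camera `u` is the sheep-to-backplane
#' distance and `v` the camera-to-backplane distance (cm); for the back
#' camera `u` is the sheep height and `v` the camera-to-ground distance.
#'
#' @param intercept model intercept.
#' @param coeffs_a linear/quadratic/cubic coefficients of the first predictor.
#' @param coeffs_b linear/quadratic/cubic coefficients of the second predictor.
#' @param range_u optional calibrated range of the first predictor (plate
#'   travel); evaluation outside it warns.
#' @param label optional preset name.
#' @return a `calibration_model`.
#' @export
calibration_model <- function(intercept, coeffs_a, coeffs_b,
                              range_u = NULL, label = NULL) {
  co <- c(intercept, coeffs_a, coeffs_b)
  if (length(co) != 7L || any(!is.finite(co))) {
    ovi_stop("model needs 7 finite coefficients", "validation_error")
  }
  structure(list(intercept = intercept,
                 coeffs_a = as.numeric(coeffs_a),
                 coeffs_b = as.numeric(coeffs_b),
                 range_u = range_u, label = label),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model%s: intercept %.4g>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"), x$intercept))
  invisible(x)
}

#' Published calibration presets
#'
#' The side- and back-camera ratio models fitted on calibration-plate sweeps
#' (side plate travel 0-50 cm, back plate travel 0-90 cm, 5-cm steps),
#' shipped with their printed coefficients. Note the back model's intercept
#' is negative: it is only meaningful inside the calibrated geometry, not at
#' the origin.
#'
#' @param name `"paper_side"` or `"paper_back"`.
#' @return a [calibration_model()].
#' @export
calibration_preset <- function(name = c("paper_side", "paper_back")) {
  name <- match.arg(name)
  if (name == "paper_side") {
    calibration_model(92.67,
                      coeffs_a = c(0.05795, -0.0008332, 0.000006949),
                      coeffs_b = c(-1.529, 0.008718, -0.00001699),
                      range_u = c(0, 50), label = name)
  } else {
    calibration_model(-40.38,
                      coeffs_a = c(0.01818, 0.0001908, 0.000001377),
                      coeffs_b = c(1.035, -0.007941, 0.00001959),
                      range_u = c(0, 90), label = name)
  }
}

#' Evaluate a calibration ratio model
#'
#' @param model a [calibration_model()].
#' @param u,v predictor values in centimeters (vectorized).
#' @return pixels-per-centimeter ratio(s).
#' @export
eval_ratio <- function(model, u, v) {
  if (!inherits(model, "calibration_model")) {
    ovi_stop("model must be a calibration_model", "validation_error")
  }
  if (!is.null(model$range_u) &&
      any(u < model$range_u[1] - 1e-9 | u > model$range_u[2] + 1e-9)) {
    warning(sprintf("evaluating outside the calibrated range [%g, %g] cm",
                    model$range_u[1], model$range_u[2]))
  }
  a <- model$coeffs_a; b <- model$coeffs_b
  model$intercept + a[1] * u + a[2] * u^2 + a[3] * u^3 +
    b[1] * v + b[2] * v^2 + b[3] * v^3
}

#' Fit a calibration model to plate observations
#'
#' Ordinary least squares on the 7-term additive cubic basis.
#'
#' @param samples data frame with columns `u`, `v` (cm) and `ratio`
#'   (pixels per cm); at least 7 rows spanning at least 4 distinct values on
#'   each predictor.
#' @return a [calibration_model()] with attribute `rmse` (root mean squared
#'   residual of the fit).
#' @export
fit_model <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("u", "v", "ratio")
  if (!all(need %in% names(samples))) {
    ovi_stop("samples need columns u, v, ratio", "validation_error")
  }
  if (nrow(samples) < 7L) {
    ovi_stop("need at least 7 calibration samples", "validation_error")
  }
  if (length(unique(samples$u)) < 4L) {
    ovi_stop("rank-deficient design: fewer than 4 distinct u values", "calibration_error")
  }
  if (length(unique(samples$v)) < 4L) {
    ovi_stop("rank-deficient design: fewer than 4 distinct v values", "calibration_error")
  }
  fit <- stats::lm(ratio ~ u + I(u^2) + I(u^3) + v + I(v^2) + I(v^3), data = samples)
  co <- stats::coef(fit)
  if (anyNA(co)) ovi_stop("rank-deficient design: collinear predictors", "calibration_error")
  m <- calibration_model(co[[1]],
                         coeffs_a = co[c("u", "I(u^2)", "I(u^3)")],
                         coeffs_b = co[c("v", "I(v^2)", "I(v^3)")],
                         range_u = range(samples$u))
  attr(m, "rmse") <- sqrt(mean(stats::residuals(fit)^2))
  m
}

#' Convert a pixel distance to centimeters
#'
#' @param px pixel distance (vectorized).
#' @param ratio pixels-per-centimeter scale; must be positive. A
#'   non-positive ratio signals evaluation outside the physically calibrated
#'   geometry (for instance the back model at the coordinate origin).
#' @return distance in centimeters.
#' @export
px_to_cm <- function(px, ratio) {
  if (!is.finite(ratio) || ratio <= 0) {
    ovi_stop("non-physical calibration: ratio must be positive", "calibration_error")
  }
  px / ratio
}

#' Read/write calibration models as YAML
#'
#' @param model a [calibration_model()].
#' @param path YAML file path.
#' @return `read_calibration` returns a [calibration_model()].
#' @export
write_calibration <- function(model, path) {
  yaml::write_yaml(list(
    intercept = model$intercept,
    coeffs_a = model$coeffs_a, coeffs_b = model$coeffs_b,
    range_u = model$range_u, label = model$label
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  calibration_model(y$intercept, unlist(y$coeffs_a), unlist(y$coeffs_b),
                    range_u = if (!is.null(y$range_u)) unlist(y$range_u),
                    label = y$label)
}
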