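# External-standard method (ESM): ordinary least squares calibration of peak
# area on concentration, Pearson r, detection limits, and back-calculation.

new_calibration_curve <- function(analyte, slope, intercept, r, range_low,
                                  range_high, lod = NA_real_, n = NA_integer_,
                                  data = NULL) {
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r = r, range_low = range_low, range_high = range_high,
                 lod = lod, n = n, data = data),
            class = "calibration_curve")
}

#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of peak area on concentration (unweighted, as for a
#' simple linear assay response), with the Pearson correlation coefficient and
#' the calibrated range `[min, max]` of the standards.
#'
#' @param points Data frame with columns `concentration` (ug/mL, > 0) and
#'   `area`; at least 3 points at 3 distinct concentrations.
#' @param analyte Optional analyte name stored on the curve.
#' @return An object of class `calibration_curve` with components `slope`,
#'   `intercept`, `r`, `range_low`, `range_high`.
#' @examples
#' x <- c(2.5, 5, 25, 50, 100, 150)
#' fit_calibration(data.frame(concentration = x, area = 20.301 * x - 1.624))
#' @export
fit_calibration <- function(points, analyte = NA_character_) {
  qk_check(is.data.frame(points) &&
             all(c("concentration", "area") %in% names(points)),
           "points must have columns concentration and area", "invalid_input")
  qk_check(all(points$concentration > 0), "concentrations must be > 0",
           "invalid_input")
  qk_check(nrow(points) >= 3 && length(unique(points$concentration)) >= 3,
           "need at least 3 points at 3 distinct concentrations",
           "insufficient_data")
  fit <- stats::lm(area ~ concentration, data = points)
  cf <- stats::coef(fit)
  r <- stats::cor(points$concentration, points$area)
  new_calibration_curve(analyte = analyte,
                        slope = unname(cf["concentration"]),
                        intercept = unname(cf["(Intercept)"]), r = r,
                        range_low = min(points$concentration),
                        range_high = max(points$concentration),
                        n = nrow(points), data = points)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: area = %.4g * conc %+ .4g, r = %.4f, range %g-%g ug/mL",
              if (is.na(x$analyte)) "(unnamed)" else x$analyte,
              x$slope, x$intercept, x$r, x$range_low, x$range_high))
  if (!is.na(x$lod)) cat(sprintf(", LOD %.3g ug/mL", x$lod))
  cat("\n")
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$slope * concentration + object$intercept
}

#' @export
residuals.calibration_curve <- function(object, ...) {
  if (is.null(object$data)) return(numeric(0))
  object$data$area - predict(object, object$data$concentration)
}

#' @export
summary.calibration_curve <- function(object, ...) {
  print(object)
  if (!is.null(object$data)) {
    res <- residuals(object)
    cat(sprintf("  %d standards, residual sd %.4g, r^2 %.6f\n",
                object$n, stats::sd(res), object$r^2))
  }
  invisible(object)
}

#' Limit of detection from noise and slope
#'
#' `LOD = 3.3 * noise_sd_area / slope`, the sd-of-blank over slope convention.
#'
#' @param curve A `calibration_curve` with positive slope.
#' @param noise_sd_area Peak-area noise standard deviation (> 0).
#' @return Detection limit in ug/mL.
#' @export
lod <- function(curve, noise_sd_area) {
  qk_check(inherits(curve, "calibration_curve"),
           "curve must be a calibration_curve", "invalid_parameter")
  qk_check(is.numeric(curve$slope) && curve$slope > 0, "slope must be > 0",
           "invalid_parameter")
  qk_check(is.numeric(noise_sd_area) && noise_sd_area > 0,
           "noise_sd_area must be > 0", "invalid_parameter")
  3.3 * noise_sd_area / curve$slope
}

#' Back-calculate concentration by the external-standard method
#'
#' `C = (area - intercept) / slope`. Concentrations outside the calibrated
#' range are flagged (warning + `in_range` attribute), not rejected; a
#' non-positive back-calculated concentration is an error.
#'
#' @param curve A `calibration_curve`.
#' @param area Peak area(s), mAU.min.
#' @return Concentration(s) in ug/mL with an `in_range` logical attribute.
#' @examples
#' cv <- fit_calibration(data.frame(concentration = c(2.5, 5, 25, 50, 100, 150),
#'                                  area = 20.301 * c(2.5, 5, 25, 50, 100, 150) - 1.624))
#' esm_quantify(cv, 1013.426)  # 50 ug/mL
#' @export
esm_quantify <- function(curve, area) {
  qk_check(inherits(curve, "calibration_curve"),
           "curve must be a calibration_curve", "invalid_parameter")
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc <= 0)) {
    qk_stop("back-calculated concentration is not positive", "out_of_domain")
  }
  in_range <- conc >= curve$range_low & conc <= curve$range_high
  if (!all(in_range)) {
    warning(sprintf("%d result(s) outside the calibrated range %g-%g ug/mL",
                    sum(!in_range), curve$range_low, curve$range_high),
            call. = FALSE)
  }
  attr(conc, "in_range") <- in_range
  conc
}

#' Simulate a calibration series at the area level
#'
#' Evaluates each analyte's packaged linear response at the given levels and
#' applies multiplicative Gaussian area noise; this is the standard-series
#' generator used for linearity studies.
#'
#' @param method An [instrument_method()].
#' @param levels Concentration levels, ug/mL.
#' @param area_cv Multiplicative area noise coefficient of variation
#'   (default 0.01, i.e. 1 %); 0 gives exact responses.
#' @param n_rep Injections per level.
#' @param seed Seed for the noise stream.
#' @return Data frame with columns `analyte`, `concentration`, `area`.
#' @export
simulate_calibration_areas <- function(method,
                                       levels = c(2.5, 5, 25, 50, 100, 150),
                                       area_cv = 0.01, n_rep = 1,
                                       seed = NULL) {
  qk_check(inherits(method, "instrument_method"),
           "method must be an instrument_method", "invalid_parameter")
  qk_check(all(levels > 0), "levels must be > 0", "invalid_parameter")
  qk_check(area_cv >= 0, "area_cv must be >= 0", "invalid_parameter")
  with_seed(seed, {
    rows <- lapply(analyte_names(method), function(nm) {
      a <- method$analytes[[nm]]
      conc <- rep(levels, each = n_rep)
      mu <- a$response_slope * conc + a$response_intercept
      area <- mu * (1 + stats::rnorm(length(mu), 0, area_cv))
      data.frame(analyte = nm, concentration = conc, area = area,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
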