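# Synthetic diode-array chromatogram generator. Peaks are symmetric Gaussians
# in time; each analyte carries a UV spectrum that scales its signal across the
# wavelength grid, and a linear area response (area = slope * conc + intercept)
# calibrated at its detection wavelength.

#' UV absorption spectrum
#'
#' A discretised UV spectrum: absorbance (arbitrary units, non-negative) on a
#' strictly ascending wavelength grid of at least 8 points.
#'
#' @param wavelengths_nm Strictly ascending numeric wavelength grid (nm).
#' @param absorbance Non-negative absorbance values, same length as the grid.
#' @return An object of class `uv_spectrum`.
#' @examples
#' s <- uv_spectrum(250:320, exp(-((250:320) - 277)^2 / (2 * 15^2)))
#' @export
uv_spectrum <- function(wavelengths_nm, absorbance) {
  qk_check(is.numeric(wavelengths_nm) && is.numeric(absorbance),
           "spectrum grids must be numeric", "invalid_input")
  qk_check(length(wavelengths_nm) == length(absorbance),
           "wavelength and absorbance grids must have equal length",
           "invalid_input")
  qk_check(length(wavelengths_nm) >= 8,
           "a spectrum needs at least 8 grid points", "invalid_input")
  qk_check(all(diff(wavelengths_nm) > 0),
           "wavelengths must be strictly ascending", "invalid_input")
  qk_check(all(absorbance >= 0), "absorbance must be non-negative",
           "invalid_input")
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 absorbance = as.numeric(absorbance)),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %d points, %g-%g nm, lambda_max %g nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm),
              x$wavelengths_nm[which.max(x$absorbance)]))
  invisible(x)
}

# Interpolate a spectrum onto arbitrary wavelengths (flat extrapolation).
spectrum_at <- function(spectrum, wavelengths_nm) {
  stats::approx(spectrum$wavelengths_nm, spectrum$absorbance,
                xout = wavelengths_nm, rule = 2)$y
}

#' Analyte description for the simulator
#'
#' Bundles the chromatographic and spectral behaviour of one analyte: apex
#' retention time, Gaussian peak width, UV spectrum, and the linear peak-area
#' response `area = response_slope * conc + response_intercept` holding at
#' `detection_wavelength_nm`.
#'
#' @param name Analyte name.
#' @param retention_min Apex retention time in minutes (> 0).
#' @param sigma_min Gaussian peak standard deviation in minutes (> 0).
#' @param uv_spectrum A [uv_spectrum()] object.
#' @param response_slope Peak-area units per (ug/mL) at the detection
#'   wavelength (> 0).
#' @param response_intercept Peak-area units (default 0).
#' @param detection_wavelength_nm Wavelength (nm) at which the response is
#'   calibrated; default 278.
#' @param qams_wavelength_nm Wavelength used for this analyte in the packaged
#'   measured relative-correction-factor table; defaults to the detection
#'   wavelength.
#' @param lod_area_sd Peak-area noise standard deviation associated with this
#'   analyte's packaged detection limit (optional, used by [lod()] fixtures).
#' @return An object of class `analyte_spec`.
#' @export
analyte_spec <- function(name, retention_min, sigma_min, uv_spectrum,
                         response_slope, response_intercept = 0,
                         detection_wavelength_nm = 278,
                         qams_wavelength_nm = detection_wavelength_nm,
                         lod_area_sd = NA_real_) {
  qk_check(is.character(name) && nzchar(name), "analyte needs a name",
           "invalid_parameter")
  qk_check(is.numeric(retention_min) && retention_min > 0,
           "retention_min must be > 0", "invalid_parameter")
  qk_check(is.numeric(sigma_min) && sigma_min > 0,
           "sigma_min must be > 0", "invalid_parameter")
  qk_check(inherits(uv_spectrum, "uv_spectrum"),
           "uv_spectrum must be a uv_spectrum object", "invalid_parameter")
  qk_check(is.numeric(response_slope) && response_slope > 0,
           "response_slope must be > 0", "invalid_parameter")
  structure(list(name = name, retention_min = retention_min,
                 sigma_min = sigma_min, uv_spectrum = uv_spectrum,
                 response_slope = response_slope,
                 response_intercept = response_intercept,
                 detection_wavelength_nm = detection_wavelength_nm,
                 qams_wavelength_nm = qams_wavelength_nm,
                 lod_area_sd = lod_area_sd),
            class = "analyte_spec")
}

#' Instrument method (separation + detection configuration)
#'
#' @param analytes List of [analyte_spec()] objects.
#' @param dead_time_marker_retention_min Retention of the unretained dead-time
#'   marker (t0 role), minutes; must elute before every analyte.
#' @param time_start,time_end,time_step Acquisition time grid in minutes;
#'   `time_end` must exceed the last apex by at least 4 peak sd.
#' @param wavelength_grid_nm Detector wavelength grid (nm).
#' @param baseline_level Constant baseline offset, mAU.
#' @param baseline_drift_per_min Linear baseline drift, mAU/min.
#' @param noise_sd Additive i.i.d. Gaussian detector noise sd, mAU (>= 0).
#' @param seed Default seed used by [render_chromatogram()] when none is given.
#' @return An object of class `instrument_method`.
#' @export
instrument_method <- function(analytes, dead_time_marker_retention_min = 1.5,
                              time_start = 0, time_end = 25,
                              time_step = 0.005,
                              wavelength_grid_nm = 230:360,
                              baseline_level = 2,
                              baseline_drift_per_min = 0.05,
                              noise_sd = 0, seed = NULL) {
  qk_check(is.list(analytes) && length(analytes) >= 1 &&
             all(vapply(analytes, inherits, logical(1), "analyte_spec")),
           "analytes must be a non-empty list of analyte_spec objects",
           "invalid_parameter")
  qk_check(time_step > 0, "time_step must be > 0", "invalid_parameter")
  qk_check(noise_sd >= 0, "noise_sd must be >= 0", "invalid_parameter")
  rts <- vapply(analytes, `[[`, numeric(1), "retention_min")
  sds <- vapply(analytes, `[[`, numeric(1), "sigma_min")
  qk_check(time_end > max(rts + 4 * sds),
           "time_end must exceed the last apex by at least 4 peak sd",
           "invalid_parameter")
  qk_check(dead_time_marker_retention_min < min(rts),
           "dead-time marker must elute before every analyte",
           "invalid_parameter")
  qk_check(all(diff(wavelength_grid_nm) > 0),
           "wavelength grid must be strictly ascending", "invalid_parameter")
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")
  structure(list(analytes = analytes,
                 dead_time_marker_retention_min = dead_time_marker_retention_min,
                 time_start = time_start, time_end = time_end,
                 time_step = time_step,
                 wavelength_grid_nm = as.numeric(wavelength_grid_nm),
                 baseline_level = baseline_level,
                 baseline_drift_per_min = baseline_drift_per_min,
                 noise_sd = noise_sd, seed = seed),
            class = "instrument_method")
}

#' @export
print.instrument_method <- function(x, ...) {
  cat(sprintf("<instrument_method> %d analytes, %g-%g min (step %g), %d wavelengths, noise sd %.3g mAU\n",
              length(x$analytes), x$time_start, x$time_end, x$time_step,
              length(x$wavelength_grid_nm), x$noise_sd))
  for (a in x$analytes)
    cat(sprintf("  %-15s rt %5.2f min  sigma %5.3f  slope %8.3f  intercept %8.3f\n",
                a$name, a$retention_min, a$sigma_min, a$response_slope,
                a$response_intercept))
  invisible(x)
}

method_time_grid <- function(method) {
  n <- round((method$time_end - method$time_start) / method$time_step)
  method$time_start + method$time_step * (0:n)
}

analyte_names <- function(method) names(method$analytes)

#' Gaussian peak profile
#'
#' `height * exp(-(t - center)^2 / (2 * sigma^2))`, the symmetric peak shape
#' used throughout the simulator.
#'
#' @param t Time(s), minutes.
#' @param center Apex time, minutes.
#' @param sigma Peak standard deviation, minutes (> 0).
#' @param height Apex height, mAU.
#' @return Numeric vector of signal values (mAU).
#' @examples
#' gaussian_peak(10, 10, 0.1, 100)  # 100 at the apex
#' @export
gaussian_peak <- function(t, center, sigma, height) {
  qk_check(is.numeric(sigma) && sigma > 0, "sigma must be > 0",
           "invalid_parameter")
  height * exp(-(t - center)^2 / (2 * sigma^2))
}

#' Render a diode-array chromatogram
#'
#' Builds the absorbance surface baseline + drift + sum of analyte peaks +
#' i.i.d. Gaussian noise. Each analyte's peak height at its detection
#' wavelength is chosen so that the integrated peak area reproduces
#' `response_slope * conc + response_intercept`; at other wavelengths the
#' signal is scaled by the analyte's UV spectrum shape (relative to the
#' detection wavelength). Identical (method, concentrations, seed) give
#' bit-identical output.
#'
#' @param method An [instrument_method()].
#' @param concentrations Named numeric vector of concentrations (ug/mL) by
#'   analyte name (missing analytes default to 0), or an unnamed vector in
#'   method analyte order (a single unnamed value is recycled to every
#'   analyte). All values must be >= 0; an analyte at 0 produces no peak.
#' @param seed Seed for the noise stream; defaults to the method's seed.
#' @param wavelengths Optional subset of wavelengths (nm) to render; defaults
#'   to the full method grid.
#' @return An object of class `chromatogram`: list with `time_min`,
#'   `wavelength_nm` and an absorbance matrix (time x wavelength, mAU).
#' @examples
#' m <- ld5_method(noise_sd = 0)
#' ch <- render_chromatogram(m, c("etacrynic acid" = 50), wavelengths = 278)
#' @export
render_chromatogram <- function(method, concentrations, seed = method$seed,
                                wavelengths = NULL) {
  qk_check(inherits(method, "instrument_method"),
           "method must be an instrument_method", "invalid_parameter")
  nms <- analyte_names(method)
  conc <- stats::setNames(numeric(length(nms)), nms)
  if (is.null(names(concentrations))) {
    qk_check(length(concentrations) %in% c(1L, length(nms)),
             "unnamed concentrations must be length 1 or one per analyte",
             "invalid_input")
    conc[] <- concentrations
  } else {
    unknown <- setdiff(names(concentrations), nms)
    qk_check(length(unknown) == 0,
             paste("unknown analyte(s):", paste(unknown, collapse = ", ")),
             "invalid_input")
    conc[names(concentrations)] <- concentrations
  }
  qk_check(all(is.finite(conc)) && all(conc >= 0),
           "concentrations must be finite and >= 0", "invalid_input")

  t <- method_time_grid(method)
  wl <- if (is.null(wavelengths)) method$wavelength_grid_nm else
    as.numeric(wavelengths)
  A <- matrix(method$baseline_level + method$baseline_drift_per_min * t,
              nrow = length(t), ncol = length(wl))
  for (nm in nms) {
    C <- conc[[nm]]
    if (C <= 0) next
    a <- method$analytes[[nm]]
    area <- max(a$response_slope * C + a$response_intercept, 0)
    if (area <= 0) next
    height <- area / (a$sigma_min * sqrt(2 * pi))
    s_det <- spectrum_at(a$uv_spectrum, a$detection_wavelength_nm)
    qk_check(s_det > 0,
             sprintf("%s has zero spectral absorbance at its detection wavelength",
                     nm), "invalid_parameter")
    scale_w <- spectrum_at(a$uv_spectrum, wl) / s_det
    g <- gaussian_peak(t, a$retention_min, a$sigma_min, height)
    A <- A + outer(g, scale_w)
  }
  if (method$noise_sd > 0) {
    A <- A + with_seed(seed,
      matrix(stats::rnorm(length(A), 0, method$noise_sd), nrow = nrow(A)))
  }
  structure(list(time_min = t, wavelength_nm = wl, absorbance = A,
                 seed = if (method$noise_sd > 0) seed else NULL),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d time points (%g-%g min) x %d wavelengths (%g-%g nm)\n",
              length(x$time_min), min(x$time_min), max(x$time_min),
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}

#' Chromatographic condition change
#'
#' Describes a small deliberate change of the separation conditions, as used
#' in robustness testing: mobile-phase pH, flow rate (fractional), column
#' temperature, organic-modifier fraction, and a multiplicative detector gain.
#'
#' @param d_pH Change in mobile-phase pH (unitless).
#' @param d_flow_frac Fractional flow-rate change (e.g. +0.02 for +2 %).
#' @param d_temp_C Column-temperature change, degrees C.
#' @param d_organic_frac Change in organic-modifier volume fraction (e.g.
#'   +0.02 for +2 percentage points of acetonitrile).
#' @param gain_factor Multiplicative detector/injection gain (> 0).
#' @return An object of class `condition_delta`.
#' @export
condition_delta <- function(d_pH = 0, d_flow_frac = 0, d_temp_C = 0,
                            d_organic_frac = 0, gain_factor = 1) {
  qk_check(is.numeric(gain_factor) && gain_factor > 0,
           "gain_factor must be > 0", "invalid_parameter")
  structure(list(d_pH = d_pH, d_flow_frac = d_flow_frac, d_temp_C = d_temp_C,
                 d_organic_frac = d_organic_frac, gain_factor = gain_factor),
            class = "condition_delta")
}

#' Default retention sensitivities of the condition model
#'
#' Retention times respond multiplicatively to condition changes:
#' `rt' = rt * (1 - d_flow_frac) * (1 + k_pH*d_pH + k_T*d_temp_C +
#' k_B*d_organic_frac)`. The defaults encode small monotone shifts: -5 % per
#' pH unit, -0.5 % per degree C, and -3 % per percentage point of organic
#' modifier (`d_organic_frac` is a fraction, hence -3 per unit).
#'
#' @return Named numeric vector with elements `k_pH`, `k_T`, `k_B`.
#' @export
default_sensitivities <- function() c(k_pH = -0.05, k_T = -0.005, k_B = -3)

#' Apply a condition change to an instrument method
#'
#' Scales analyte retention times by
#' `(1 - d_flow_frac) * (1 + k_pH*d_pH + k_T*d_temp_C + k_B*d_organic_frac)`,
#' scales the dead-time marker by flow only, and multiplies every response
#' slope by `gain_factor`. The input method is not modified.
#'
#' @param method An [instrument_method()].
#' @param delta A [condition_delta()].
#' @param sensitivities Named vector as from [default_sensitivities()].
#' @return A new `instrument_method`.
#' @export
perturb_method <- function(method, delta,
                           sensitivities = default_sensitivities()) {
  qk_check(inherits(method, "instrument_method"),
           "method must be an instrument_method", "invalid_parameter")
  qk_check(inherits(delta, "condition_delta"),
           "delta must be a condition_delta", "invalid_parameter")
  f_flow <- 1 - delta$d_flow_frac
  f_cond <- 1 + sensitivities[["k_pH"]] * delta$d_pH +
    sensitivities[["k_T"]] * delta$d_temp_C +
    sensitivities[["k_B"]] * delta$d_organic_frac
  f_ret <- f_flow * f_cond
  qk_check(f_ret > 0 && f_flow > 0,
           "condition change would produce non-positive retention",
           "invalid_parameter")
  out <- method
  out$dead_time_marker_retention_min <-
    method$dead_time_marker_retention_min * f_flow
  out$analytes <- lapply(method$analytes, function(a) {
    a$retention_min <- a$retention_min * f_ret
    qk_check(a$retention_min > 0, "non-positive retention after perturbation",
             "invalid_parameter")
    a$response_slope <- a$response_slope * delta$gain_factor
    a$response_intercept <- a$response_intercept * delta$gain_factor
    a
  })
  qk_check(out$dead_time_marker_retention_min <
             min(vapply(out$analytes, `[[`, numeric(1), "retention_min")),
           "perturbation moved the dead-time marker past an analyte",
           "invalid_parameter")
  out
}
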