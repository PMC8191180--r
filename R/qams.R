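# Single-marker quantification: relative correction factors (RCF) and
# back-calculation of analyte concentrations from the internal reference.
# RCF = (As/Cs) / (Ai/Ci): the ratio of the reference's response factor to
# the analyte's. Ci = RCF * Cs * Ai / As.

#' Reference measurement (area + known concentration)
#'
#' A single analyte measurement pairing a peak area with the known
#' concentration it came from, as used to establish or apply relative
#' correction factors.
#'
#' @param analyte Analyte name.
#' @param area Peak area, mAU.min (> 0).
#' @param concentration Concentration, ug/mL (> 0).
#' @param wavelength_nm Wavelength the area was integrated at.
#' @return An object of class `ref_measurement`.
#' @export
ref_measurement <- function(analyte, area, concentration,
                            wavelength_nm = NA_real_) {
  qk_check(is.numeric(area) && length(area) == 1 && area > 0,
           "area must be a single positive number", "invalid_input")
  qk_check(is.numeric(concentration) && length(concentration) == 1 &&
             concentration > 0,
           "concentration must be a single positive number", "invalid_input")
  structure(list(analyte = analyte, area = unname(area),
                 concentration = unname(concentration),
                 wavelength_nm = wavelength_nm),
            class = "ref_measurement")
}

#' Relative correction factor from a paired run
#'
#' `RCF = (As/Cs) / (Ai/Ci)` from one paired measurement of the internal
#' reference (s) and the analyte (i). Invariant under any common
#' multiplicative scaling of both areas (detector gain cancels).
#'
#' @param ref [ref_measurement()] of the internal reference.
#' @param analyte [ref_measurement()] of the analyte.
#' @return An object of class `rcf_record` with fields `analyte`,
#'   `reference`, `rcf`, `wavelength_nm`, `rsd_pct` (NA until a robustness
#'   study fills it).
#' @examples
#' s <- ref_measurement("etacrynic acid", 2000, 50)
#' i <- ref_measurement("torasemide", 1000, 50)
#' compute_rcf(s, i)$rcf  # 2
#' @export
compute_rcf <- function(ref, analyte) {
  qk_check(inherits(ref, "ref_measurement") &&
             inherits(analyte, "ref_measurement"),
           "ref and analyte must be ref_measurement objects", "invalid_input")
  rcf <- (ref$area / ref$concentration) / (analyte$area / analyte$concentration)
  structure(list(analyte = analyte$analyte, reference = ref$analyte,
                 rcf = rcf, wavelength_nm = analyte$wavelength_nm,
                 rsd_pct = NA_real_),
            class = "rcf_record")
}

#' @export
print.rcf_record <- function(x, ...) {
  cat(sprintf("<rcf_record> %s vs %s: RCF %.4f", x$analyte, x$reference,
              x$rcf))
  if (!is.na(x$wavelength_nm)) cat(sprintf(" @ %g nm", x$wavelength_nm))
  if (!is.na(x$rsd_pct)) cat(sprintf(" (robustness RSD %.2f %%)", x$rsd_pct))
  cat("\n")
  invisible(x)
}

#' Relative correction factor from calibration slopes
#'
#' Slope-ratio variant: `RCF = slope_ref / slope_analyte`, ignoring the
#' intercepts. Warns when either intercept is material (|b| more than 2 % of
#' the response at the bottom of the calibrated range), since the single-run
#' definition and the slope ratio then diverge.
#'
#' @param ref_curve,analyte_curve `calibration_curve` objects.
#' @return An `rcf_record`.
#' @export
rcf_from_slopes <- function(ref_curve, analyte_curve) {
  qk_check(inherits(ref_curve, "calibration_curve") &&
             inherits(analyte_curve, "calibration_curve"),
           "inputs must be calibration_curve objects", "invalid_input")
  for (cv in list(ref_curve, analyte_curve)) {
    rel <- abs(cv$intercept) / (cv$slope * cv$range_low)
    if (is.finite(rel) && rel > 0.02) {
      warning(sprintf("intercept of %s is %.1f %% of the low-range response; slope-ratio RCF ignores it",
                      cv$analyte, 100 * rel), call. = FALSE)
    }
  }
  structure(list(analyte = analyte_curve$analyte,
                 reference = ref_curve$analyte,
                 rcf = ref_curve$slope / analyte_curve$slope,
                 wavelength_nm = NA_real_, rsd_pct = NA_real_),
            class = "rcf_record")
}

#' Quantify an analyte by the single-marker method
#'
#' `Ci = RCF * Cs * Ai / As`: back-calculates the analyte concentration from
#' its peak area, the internal reference's area and known concentration, and
#' the pre-established relative correction factor.
#'
#' @param rcf An `rcf_record` (or a single positive number).
#' @param ref [ref_measurement()] of the internal reference in the same run.
#' @param analyte_area Analyte peak area(s), mAU.min (> 0).
#' @return Concentration(s) in ug/mL.
#' @examples
#' s <- ref_measurement("etacrynic acid", 1013.4, 50)
#' qams_quantify(0.9024, s, 1013.4)  # 45.12 ug/mL
#' @export
qams_quantify <- function(rcf, ref, analyte_area) {
  rcf_val <- if (inherits(rcf, "rcf_record")) rcf$rcf else rcf
  qk_check(is.numeric(rcf_val) && length(rcf_val) == 1 && rcf_val > 0,
           "rcf must be a single positive number", "invalid_input")
  qk_check(inherits(ref, "ref_measurement"),
           "ref must be a ref_measurement", "invalid_input")
  qk_check(is.numeric(analyte_area) && all(analyte_area > 0),
           "analyte_area must be positive", "invalid_input")
  unname(rcf_val * ref$concentration * analyte_area / ref$area)
}

#' Robustness of relative correction factors across conditions
#'
#' Pools per-condition RCF determinations into per-analyte mean RCF and
#' relative standard deviation (sample sd, n-1).
#'
#' @param rcf_sets A list with one element per condition; each element is a
#'   list of `rcf_record`s (or a data frame with `analyte` and `rcf`
#'   columns).
#' @return Data frame with columns `analyte`, `mean_rcf`, `rsd_pct`,
#'   `n_conditions`.
#' @export
rcf_robustness <- function(rcf_sets) {
  qk_check(is.list(rcf_sets) && length(rcf_sets) >= 2,
           "need at least 2 conditions", "invalid_input")
  norm_one <- function(set) {
    if (is.data.frame(set)) {
      data.frame(analyte = set$analyte, rcf = set$rcf,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(analyte = vapply(set, `[[`, character(1), "analyte"),
                 rcf = vapply(set, `[[`, numeric(1), "rcf"),
                 stringsAsFactors = FALSE)
    }
  }
  tabs <- lapply(rcf_sets, norm_one)
  analytes <- unique(unlist(lapply(tabs, `[[`, "analyte")))
  for (i in seq_along(tabs)) {
    missing <- setdiff(analytes, tabs[[i]]$analyte)
    qk_check(length(missing) == 0,
             sprintf("condition %d is missing analyte(s): %s", i,
                     paste(missing, collapse = ", ")), "incomplete_grid")
  }
  rows <- lapply(analytes, function(nm) {
    vals <- vapply(tabs, function(tb) tb$rcf[match(nm, tb$analyte)],
                   numeric(1))
    data.frame(analyte = nm, mean_rcf = mean(vals), rsd_pct = rsd(vals),
               n_conditions = length(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
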