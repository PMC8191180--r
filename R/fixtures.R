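# Packaged five loop-diuretic assay fixture. Elution order torasemide,
# furosemide, azosemide, etacrynic acid, bumetanide with apices at
# 4.8/6.3/7.6/9.7/18.5 min; linear area responses at 278 nm; per-analyte UV
# maxima at 292/334/326/277/260 nm. The true UV spectra of the five drugs are
# not published, so each packaged spectrum is a synthetic mixture of 2-3
# wavelength Gaussians placed at the reported maxima: distinct, realistic
# chromophores for similarity testing without pretending to be measured data.

ld5_params <- function() {
  data.frame(
    analyte   = c("torasemide", "furosemide", "azosemide", "etacrynic acid",
                  "bumetanide"),
    retention_min = c(4.8, 6.3, 7.6, 9.7, 18.5),
    # sigma = t / sqrt(N) with N ~ 8000 plates (150 x 4.6 mm, 5 um column)
    sigma_min = c(0.054, 0.070, 0.085, 0.108, 0.207),
    slope     = c(33.204, 27.634, 43.381, 20.301, 36.124),
    intercept = c(3.131, -0.970, 8.666, -1.624, 1.320),
    r_ref     = c(0.9998, 0.9999, 0.9992, 0.9993, 0.9999),
    lod       = c(0.08, 0.05, 0.13, 0.25, 0.20),
    qams_wavelength_nm = c(292, 334, 326, 277, 260),
    rcf       = c(0.3232, 0.9024, 0.8064, 1, 0.5566),
    rcf_rsd_pct = c(0.18, 0.35, 0.63, NA, 0.67),
    stringsAsFactors = FALSE
  )
}

gauss_mix_spectrum <- function(grid, bands) {
  a <- rowSums(vapply(bands, function(b)
    b[3] * exp(-(grid - b[1])^2 / (2 * b[2]^2)), numeric(length(grid))))
  uv_spectrum(grid, a)
}

#' Packaged synthetic UV spectra of the five loop diuretics
#'
#' Each spectrum is a mixture of 2-3 Gaussians in wavelength with the main
#' band at the analyte's reference wavelength (292, 334, 326, 277 and 260 nm
#' for torasemide, furosemide, azosemide, etacrynic acid and bumetanide).
#' These are synthetic stand-ins for the unpublished measured spectra.
#'
#' @param grid Wavelength grid (nm); default 230-360 nm in 1 nm steps.
#' @return Named list of [uv_spectrum()] objects.
#' @export
ld5_spectra <- function(grid = 230:360) {
  list(
    "torasemide"     = gauss_mix_spectrum(grid, list(c(292, 20, 1), c(242, 12, 0.45))),
    "furosemide"     = gauss_mix_spectrum(grid, list(c(334, 16, 1), c(273, 15, 0.65),
                                                     c(236, 10, 0.5))),
    "azosemide"      = gauss_mix_spectrum(grid, list(c(326, 17, 1), c(258, 13, 0.6))),
    "etacrynic acid" = gauss_mix_spectrum(grid, list(c(277, 18, 1), c(232, 14, 0.55))),
    "bumetanide"     = gauss_mix_spectrum(grid, list(c(260, 15, 1), c(328, 22, 0.35)))
  )
}

#' Packaged five loop-diuretic instrument method
#'
#' The reference separation: five analytes with apices at 4.8, 6.3, 7.6, 9.7
#' and 18.5 min, linear area responses calibrated at 278 nm, dead-time marker
#' at 1.5 min, 0-25 min acquisition at 0.005 min steps, 230-360 nm detection.
#' The default noise sd is chosen so that the integrated peak-area CV of the
#' internal reference (etacrynic acid) is about 0.5 % at 50 ug/mL, the scale
#' of routine injection repeatability.
#'
#' @param noise_sd Detector noise sd in mAU; `NULL` (default) picks the value
#'   giving ~0.5 % reference-peak area CV at 50 ug/mL; 0 disables noise.
#' @param time_step Acquisition step, minutes.
#' @param wavelength_grid_nm Detector wavelength grid.
#' @param ... Passed on to [instrument_method()].
#' @return An [instrument_method()] with five `analyte_spec` entries.
#' @examples
#' m <- ld5_method(noise_sd = 0)
#' vapply(m$analytes, `[[`, numeric(1), "retention_min")
#' @export
ld5_method <- function(noise_sd = NULL, time_step = 0.005,
                       wavelength_grid_nm = 230:360, ...) {
  p <- ld5_params()
  spectra <- ld5_spectra()
  if (is.null(noise_sd)) {
    # area sd from trapezoidal integration over ~8 sigma: sd_area =
    # noise_sd * sqrt(step * 8 sigma); target 0.5 % of the reference area at 50.
    i <- match("etacrynic acid", p$analyte)
    target <- 0.005 * (p$slope[i] * 50 + p$intercept[i])
    noise_sd <- target / sqrt(time_step * 8 * p$sigma_min[i])
  }
  analytes <- lapply(seq_len(nrow(p)), function(i) {
    analyte_spec(name = p$analyte[i], retention_min = p$retention_min[i],
                 sigma_min = p$sigma_min[i], uv_spectrum = spectra[[p$analyte[i]]],
                 response_slope = p$slope[i], response_intercept = p$intercept[i],
                 detection_wavelength_nm = 278,
                 qams_wavelength_nm = p$qams_wavelength_nm[i],
                 lod_area_sd = p$lod[i] * p$slope[i] / 3.3)
  })
  instrument_method(analytes, dead_time_marker_retention_min = 1.5,
                    time_step = time_step,
                    wavelength_grid_nm = wavelength_grid_nm,
                    noise_sd = noise_sd, ...)
}

#' Packaged measured relative correction factors
#'
#' The reference RCF table of the five-diuretic assay: per-analyte measurement
#' wavelength, robustness RSD and relative correction factor versus etacrynic
#' acid (RCF 1 by definition). These are the assay's reported values and are
#' carried as data because they were measured at per-analyte wavelengths
#' (277-334 nm) that cannot be reconstructed from the 278 nm responses.
#'
#' @return Data frame with columns `analyte`, `wavelength_nm`, `rsd_pct`,
#'   `rcf`.
#' @export
ld5_rcf_table <- function() {
  p <- ld5_params()
  data.frame(analyte = p$analyte, wavelength_nm = p$qams_wavelength_nm,
             rsd_pct = p$rcf_rsd_pct, rcf = p$rcf, stringsAsFactors = FALSE)
}

#' Packaged qualitative reference library
#'
#' Per-analyte reference relative retention times (etacrynic acid reference,
#' dead-time marker at the packaged 1.5 min) and the packaged UV spectra, for
#' use with [identify_analyte()].
#'
#' @return Named list; each entry has `analyte`, `rrt_ref` and `spectrum`.
#' @export
ld5_rrt_library <- function() {
  p <- ld5_params()
  spectra <- ld5_spectra()
  t0 <- 1.5
  tR <- p$retention_min[match("etacrynic acid", p$analyte)]
  out <- lapply(seq_len(nrow(p)), function(i) {
    list(analyte = p$analyte[i],
         rrt_ref = (p$retention_min[i] - t0) / (tR - t0),
         spectrum = spectra[[p$analyte[i]]])
  })
  stats::setNames(out, p$analyte)
}

#' Packaged external-standard calibration curves
#'
#' Calibration-curve objects built from the packaged linear responses
#' (area = slope * conc + intercept at 278 nm), valid over 2.5-150 ug/mL,
#' with the packaged detection limits attached.
#'
#' @return Named list of `calibration_curve` objects.
#' @export
ld5_curves <- function() {
  p <- ld5_params()
  out <- lapply(seq_len(nrow(p)), function(i) {
    new_calibration_curve(analyte = p$analyte[i], slope = p$slope[i],
                          intercept = p$intercept[i], r = p$r_ref[i],
                          range_low = 2.5, range_high = 150,
                          lod = p$lod[i], n = NA_integer_)
  })
  stats::setNames(out, p$analyte)
}
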