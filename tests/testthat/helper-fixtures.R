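# Small fast fixtures used across tests; the full five-diuretic method
# (ld5_method) is reserved for the tests that exercise the packaged assay.

simple_spectrum <- function(center = 260, width = 12, grid = 240:280) {
  uv_spectrum(grid, exp(-(grid - center)^2 / (2 * width^2)))
}

tiny_method <- function(noise_sd = 0, intercepts = c(0, 0), ...) {
  a1 <- analyte_spec("alpha", retention_min = 2.0, sigma_min = 0.05,
                     uv_spectrum = simple_spectrum(255),
                     response_slope = 10, response_intercept = intercepts[1],
                     detection_wavelength_nm = 260)
  a2 <- analyte_spec("beta", retention_min = 3.5, sigma_min = 0.06,
                     uv_spectrum = simple_spectrum(268),
                     response_slope = 20, response_intercept = intercepts[2],
                     detection_wavelength_nm = 260)
  instrument_method(list(a1, a2), dead_time_marker_retention_min = 0.8,
                    time_start = 0, time_end = 6, time_step = 0.005,
                    wavelength_grid_nm = 240:280, baseline_level = 1,
                    baseline_drift_per_min = 0.02, noise_sd = noise_sd, ...)
}

# one detected + matched injection on the 278 nm trace of the ld5 assay
ld5_measure <- function(method, conc, seed = NULL) {
  ch <- render_chromatogram(method, conc, seed = seed, wavelengths = 278)
  tr <- get_trace(ch, 278)
  detect_peaks(tr)
}
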