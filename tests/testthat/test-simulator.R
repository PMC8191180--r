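test_that("gaussian peak shape evaluates correctly", {
  expect_equal(gaussian_peak(10, 10, 0.1, 100), 100)
  expect_equal(gaussian_peak(10.1, 10, 0.1, 100), 100 * exp(-0.5),
               tolerance = 1e-12)
  expect_lt(gaussian_peak(11, 10, 0.1, 100), 1e-15)
  expect_error(gaussian_peak(1, 1, 0, 10), class = "qamskit_invalid_parameter")
  expect_error(gaussian_peak(1, 1, -0.1, 10),
               class = "qamskit_invalid_parameter")
})

test_that("rendering with no analytes and no noise gives the flat baseline", {
  m <- tiny_method(noise_sd = 0)
  m$baseline_drift_per_min <- 0
  ch <- render_chromatogram(m, c(alpha = 0, beta = 0))
  expect_true(all(abs(ch$absorbance - m$baseline_level) < 1e-12))
})

test_that("analyte signals are additive with noise disabled", {
  m <- tiny_method(noise_sd = 0)
  m$baseline_level <- 0
  m$baseline_drift_per_min <- 0
  both <- render_chromatogram(m, c(alpha = 30, beta = 40))
  only_a <- render_chromatogram(m, c(alpha = 30))
  only_b <- render_chromatogram(m, c(beta = 40))
  expect_equal(both$absorbance, only_a$absorbance + only_b$absorbance,
               tolerance = 1e-12)
})

test_that("identical seeds give bit-identical chromatograms", {
  m <- tiny_method(noise_sd = 5)
  c1 <- render_chromatogram(m, c(alpha = 30, beta = 40), seed = 99)
  c2 <- render_chromatogram(m, c(alpha = 30, beta = 40), seed = 99)
  c3 <- render_chromatogram(m, c(alpha = 30, beta = 40), seed = 100)
  expect_identical(c1$absorbance, c2$absorbance)
  expect_false(identical(c1$absorbance, c3$absorbance))
})

test_that("rendering rejects negative concentrations and unknown analytes", {
  m <- tiny_method()
  expect_error(render_chromatogram(m, c(alpha = -1)),
               class = "qamskit_invalid_input")
  expect_error(render_chromatogram(m, c(gamma = 5)),
               class = "qamskit_invalid_input")
})

test_that("rendered single-peak area reproduces the linear response", {
  m <- tiny_method(noise_sd = 0, intercepts = c(1.5, -0.8))
  for (conc in c(5, 50, 120)) {
    ch <- render_chromatogram(m, c(alpha = conc), wavelengths = 260)
    tr <- get_trace(ch, 260)
    pk <- detect_peaks(tr)
    expect_equal(nrow(pk), 1)
    expect_equal(pk$area, 10 * conc + 1.5, tolerance = 1e-3)
  }
})

test_that("the packaged five-diuretic fixture elutes at the assay apices", {
  m <- ld5_method(noise_sd = 0)
  rts <- vapply(m$analytes, `[[`, numeric(1), "retention_min")
  expect_equal(unname(rts), c(4.8, 6.3, 7.6, 9.7, 18.5))
  expect_equal(names(rts), c("torasemide", "furosemide", "azosemide",
                             "etacrynic acid", "bumetanide"))
  slopes <- vapply(m$analytes, `[[`, numeric(1), "response_slope")
  expect_equal(unname(slopes), c(33.204, 27.634, 43.381, 20.301, 36.124))
})

test_that("condition perturbation follows the documented retention model", {
  m <- tiny_method()
  # identity
  same <- perturb_method(m, condition_delta())
  expect_equal(vapply(same$analytes, `[[`, numeric(1), "retention_min"),
               vapply(m$analytes, `[[`, numeric(1), "retention_min"))
  # +2 % flow scales every retention (and the marker) by exactly 0.98
  fast <- perturb_method(m, condition_delta(d_flow_frac = 0.02))
  expect_equal(vapply(fast$analytes, `[[`, numeric(1), "retention_min"),
               0.98 * vapply(m$analytes, `[[`, numeric(1), "retention_min"))
  expect_equal(fast$dead_time_marker_retention_min,
               0.98 * m$dead_time_marker_retention_min)
  # pure gain doubles slopes, leaves retention untouched
  hot <- perturb_method(m, condition_delta(gain_factor = 2))
  expect_equal(vapply(hot$analytes, `[[`, numeric(1), "response_slope"),
               2 * vapply(m$analytes, `[[`, numeric(1), "response_slope"))
  expect_equal(vapply(hot$analytes, `[[`, numeric(1), "retention_min"),
               vapply(m$analytes, `[[`, numeric(1), "retention_min"))
  # the input method is never modified
  expect_equal(m$analytes$alpha$retention_min, 2.0)
  # a change large enough to kill retention is rejected
  expect_error(perturb_method(m, condition_delta(d_flow_frac = 1.5)),
               class = "qamskit_invalid_parameter")
})

test_that("method constructor enforces its invariants", {
  a <- analyte_spec("x", 2, 0.05, simple_spectrum(), 10)
  expect_error(instrument_method(list(a), time_end = 2.1,
                                 wavelength_grid_nm = 240:280),
               class = "qamskit_invalid_parameter")
  expect_error(instrument_method(list(a),
                                 dead_time_marker_retention_min = 2.5,
                                 time_end = 6,
                                 wavelength_grid_nm = 240:280),
               class = "qamskit_invalid_parameter")
  expect_error(analyte_spec("x", -1, 0.05, simple_spectrum(), 10),
               class = "qamskit_invalid_parameter")
  expect_error(uv_spectrum(1:4, rep(1, 4)), class = "qamskit_invalid_input")
})
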