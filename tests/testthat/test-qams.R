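test_that("the relative correction factor follows its defining ratio", {
  expect_equal(compute_rcf(ref_measurement("s", 1000, 50),
                           ref_measurement("i", 1000, 50))$rcf, 1)
  expect_equal(compute_rcf(ref_measurement("s", 2000, 50),
                           ref_measurement("i", 1000, 50))$rcf, 2)
  expect_error(ref_measurement("s", -5, 50), class = "qamskit_invalid_input")
  expect_error(ref_measurement("s", 5, 0), class = "qamskit_invalid_input")
})

test_that("slope-ratio RCF matches the ratio of packaged responses", {
  x <- c(2.5, 5, 25, 50, 100, 150)
  eta <- fit_calibration(data.frame(concentration = x, area = 20.301 * x),
                         analyte = "etacrynic acid")
  tor <- fit_calibration(data.frame(concentration = x, area = 33.204 * x),
                         analyte = "torasemide")
  expect_equal(rcf_from_slopes(eta, tor)$rcf, 0.6114, tolerance = 1e-4)
  # a material intercept triggers the divergence warning
  tor_b <- fit_calibration(data.frame(concentration = x,
                                      area = 33.204 * x + 10),
                           analyte = "torasemide")
  expect_warning(rcf_from_slopes(eta, tor_b), "intercept")
})

test_that("RCF is invariant under common multiplicative gain", {
  set.seed(404)
  for (i in 1:50) {
    As <- runif(1, 100, 5000); Ai <- runif(1, 100, 5000)
    Cs <- runif(1, 5, 150); Ci <- runif(1, 5, 150)
    g <- runif(1, 0.1, 10)
    r1 <- compute_rcf(ref_measurement("s", As, Cs),
                      ref_measurement("i", Ai, Ci))$rcf
    r2 <- compute_rcf(ref_measurement("s", g * As, Cs),
                      ref_measurement("i", g * Ai, Ci))$rcf
    expect_equal(r2, r1, tolerance = 1e-12)
  }
})

test_that("single-marker back-calculation follows Ci = RCF * Cs * Ai / As", {
  s <- ref_measurement("etacrynic acid", 1013.4, 50)
  expect_equal(qams_quantify(1, s, 1013.4), 50)
  expect_equal(qams_quantify(0.9024, s, 1013.4), 45.12, tolerance = 1e-10)
  s100 <- ref_measurement("etacrynic acid", 800, 100)
  expect_equal(qams_quantify(0.5, s100, 1600), 100)
  expect_error(qams_quantify(-1, s, 10), class = "qamskit_invalid_input")
  expect_error(qams_quantify(1, s, 0), class = "qamskit_invalid_input")
})

test_that("RCF/back-calculation round trip recovers the true concentration", {
  # zero-intercept linear responses: RCF from one pair, applied to another
  slopes <- c(s = 20, i = 35)
  for (C in c(5, 50, 140)) {
    rcf <- compute_rcf(ref_measurement("s", slopes["s"] * 50, 50),
                       ref_measurement("i", slopes["i"] * 50, 50))
    run_ref <- ref_measurement("s", slopes["s"] * 80, 80)
    expect_equal(qams_quantify(rcf, run_ref, slopes["i"] * C), C,
                 tolerance = 1e-10)
  }
})

test_that("ESM and QAMS agree exactly for noiseless zero-intercept responses", {
  m <- tiny_method(noise_sd = 0, intercepts = c(0, 0))
  x <- c(2.5, 5, 25, 50, 100, 150)
  pts <- simulate_calibration_areas(m, x, area_cv = 0)
  curves <- lapply(split(pts, pts$analyte), fit_calibration)
  rcf <- rcf_from_slopes(curves$alpha, curves$beta)
  for (C in c(5, 40, 120)) {
    area_a <- 10 * 50  # reference alpha at 50 ug/mL
    area_b <- 20 * C
    esm <- as.numeric(suppressWarnings(esm_quantify(curves$beta, area_b)))
    qams <- qams_quantify(rcf, ref_measurement("alpha", area_a, 50), area_b)
    expect_equal(qams, esm, tolerance = 1e-12)
    expect_equal(qams, C, tolerance = 1e-12)
  }
})

test_that("RCF robustness pools conditions into mean and RSD", {
  mk <- function(r) list(structure(list(analyte = "i", reference = "s",
                                        rcf = r, wavelength_nm = NA,
                                        rsd_pct = NA),
                                   class = "rcf_record"))
  same <- rcf_robustness(list(mk(0.9), mk(0.9), mk(0.9)))
  expect_equal(same$rsd_pct, 0)
  spread <- rcf_robustness(list(mk(1.0), mk(1.01), mk(0.99)))
  expect_equal(spread$mean_rcf, 1)
  expect_equal(spread$rsd_pct, 1, tolerance = 1e-10)
  expect_error(rcf_robustness(list(mk(1))), class = "qamskit_invalid_input")
  bad <- list(mk(1), list(structure(list(analyte = "other", reference = "s",
                                         rcf = 1, wavelength_nm = NA,
                                         rsd_pct = NA),
                                    class = "rcf_record")))
  expect_error(rcf_robustness(bad), class = "qamskit_incomplete_grid")
})

test_that("pure detector-gain changes leave measured RCFs unchanged", {
  m <- tiny_method(noise_sd = 0, intercepts = c(0, 0))
  rcf_at_gain <- function(g) {
    pm <- perturb_method(m, condition_delta(gain_factor = g))
    ch <- render_chromatogram(pm, c(alpha = 50, beta = 50), wavelengths = 260)
    pk <- match_peaks(detect_peaks(get_trace(ch, 260)), pm)
    a <- setNames(pk$area, pk$analyte)
    compute_rcf(ref_measurement("alpha", a[["alpha"]], 50),
                ref_measurement("beta", a[["beta"]], 50))$rcf
  }
  rcfs <- vapply(c(0.5, 1, 2), rcf_at_gain, numeric(1))
  expect_lt(rsd(rcfs), 1e-5)
})

test_that("the packaged measured RCF table carries the assay values", {
  tab <- ld5_rcf_table()
  expect_equal(tab$rcf[match(c("torasemide", "furosemide", "azosemide",
                               "bumetanide", "etacrynic acid"),
                             tab$analyte)],
               c(0.3232, 0.9024, 0.8064, 0.5566, 1))
  expect_equal(tab$wavelength_nm[match("furosemide", tab$analyte)], 334)
  expect_true(all(tab$rsd_pct <= 0.67, na.rm = TRUE))
})
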