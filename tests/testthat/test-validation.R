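test_that("relative standard deviation uses the sample sd over the mean", {
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_equal(rsd(c(99, 101)), 1.4142, tolerance = 1e-4)
  expect_error(rsd(c(-1, 1)), class = "qamskit_undefined_rsd")
  expect_error(rsd(5), class = "qamskit_invalid_input")
  # invariant to multiplicative rescaling
  set.seed(3)
  x <- runif(6, 1, 10)
  expect_equal(rsd(7.7 * x), rsd(x), tolerance = 1e-12)
})

test_that("a noiseless drift-free system has zero precision RSDs", {
  m <- tiny_method(noise_sd = 0)
  prec <- run_precision(m, conc = 50, n_intra = 2, n_days = 2,
                        day_gain_sd = 0, seed = 1)
  expect_true(all(abs(prec$intraday_rsd_pct) < 1e-9))
  expect_true(all(abs(prec$interday_rsd_pct) < 1e-9))
  expect_error(run_precision(m, n_intra = 1, n_days = 2),
               class = "qamskit_invalid_parameter")
})

test_that("intraday area RSDs sit in the assay's repeatability band", {
  m <- ld5_method()
  meds <- vapply(1:6, function(s) {
    prec <- run_precision(m, n_intra = 6, n_days = 2, seed = s)
    stats::median(prec$intraday_rsd_pct)
  }, numeric(1))
  expect_true(all(meds >= 0.1 & meds <= 1.5))
})

test_that("day-level drift makes interday precision worse than intraday", {
  m <- ld5_method()
  d <- vapply(1:4, function(s) {
    prec <- run_precision(m, n_intra = 3, n_days = 3, day_gain_sd = 0.02,
                          seed = s)
    mean(prec$interday_rsd_pct - prec$intraday_rsd_pct)
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("recovery is exactly 100 percent for a noiseless unbiased system", {
  m <- tiny_method(noise_sd = 0, intercepts = c(0, 0))
  rec <- run_recovery(m, base_conc = 50, spike_levels = c(40, 50, 60),
                      n_rep = 1, seed = 1)
  expect_equal(rec$summary$mean_recovery_pct, c(100, 100),
               tolerance = 1e-4)
  expect_equal(rec$per_level$recovery_pct, rep(100, 6), tolerance = 1e-4)
  expect_error(run_recovery(m, spike_levels = c(-10)),
               class = "qamskit_invalid_parameter")
})

test_that("simulated spike recoveries fall inside the assay's accuracy band", {
  rec <- run_recovery(ld5_method(), seed = 7)
  expect_true(all(rec$summary$mean_recovery_pct >= 97.2 &
                    rec$summary$mean_recovery_pct <= 102.1))
  expect_true(all(rec$summary$rsd_pct < 1.9))
})

test_that("stability RSD is zero without decay or noise and grows with decay", {
  m <- tiny_method(noise_sd = 0)
  flat <- run_stability(m, seed = 1)
  expect_true(all(abs(flat$rsd_pct) < 1e-9))
  short <- run_stability(m, timepoints = c(0, 1, 2), degradation_rate = 0.01,
                         seed = 1)
  long <- run_stability(m, timepoints = c(0, 1, 2, 4, 6, 8),
                        degradation_rate = 0.01, seed = 1)
  expect_true(all(long$rsd_pct > short$rsd_pct))
  expect_error(run_stability(m, degradation_rate = -1),
               class = "qamskit_invalid_parameter")
})

test_that("solution stability over 8 hours stays inside the assay band", {
  stab <- run_stability(ld5_method(), seed = 5)
  expect_true(all(stab$rsd_pct <= 1.3))
})

test_that("an all-identical condition grid gives zero robustness RSDs", {
  m <- tiny_method(noise_sd = 0)
  grid <- data.frame(factor = "none", level = c(1, 2),
                     d_pH = 0, d_flow_frac = 0, d_temp_C = 0,
                     d_organic_frac = 0)
  rob <- run_robustness(m, grid, conc = 50, n_rep = 1, reference = "beta",
                        seed = 1)
  expect_true(all(abs(rob$rrt_rsd$rsd_pct) < 1e-9))
  expect_true(all(abs(rob$rcf$rsd_pct) < 1e-9))
})

test_that("assay-magnitude condition changes keep separation and identity", {
  rob <- run_robustness(ld5_method(), seed = 1)
  expect_gt(rob$min_resolution, 1.5)
  expect_lt(max(rob$rrt_rsd$rsd_pct), 5)
  expect_lte(max(rob$rcf$rsd_pct), 0.67)
  expect_equal(length(rob$failed_conditions), 0)
  # mean +/- 3S acceptance bands are finite and ordered
  expect_true(all(rob$rrt_bands$lower_3s < rob$rrt_bands$upper_3s))
})

test_that("independent per-analyte retention rescaling breaks RRT robustness", {
  surr <- run_column_surrogate(ld5_method(), n_columns = 3, seed = 9)
  expect_gt(max(surr$rsd_pct), 5)
})

test_that("ESM and QAMS coincide for a noiseless zero-intercept system", {
  m <- tiny_method(noise_sd = 0, intercepts = c(0, 0))
  cmp <- compare_esm_qams(m, sample_conc = 50, n_samples = 3,
                          reference = "alpha", seed = 1)
  expect_equal(cmp$per_analyte$esm_accuracy_pct, c(100, 100),
               tolerance = 1e-4)
  expect_equal(cmp$per_analyte$qams_accuracy_pct, c(100, 100),
               tolerance = 1e-4)
  expect_lt(max(cmp$per_analyte$rel_diff_sd_pct, na.rm = TRUE), 1e-3)
  expect_error(compare_esm_qams(m, reference = "nope"),
               class = "qamskit_missing_reference")
})

test_that("a biased reference response shifts QAMS but not ESM", {
  # Eq.-level sensitivity: inflating the reference area by 5 % with the
  # reference concentration held fixed scales the single-marker result by
  # 1/1.05 while the analyte's own external-standard result is untouched.
  curve <- fit_calibration(data.frame(concentration = c(10, 50, 100),
                                      area = 20 * c(10, 50, 100)))
  Ai <- 20 * 50
  esm <- as.numeric(esm_quantify(curve, Ai))
  q_ok <- qams_quantify(1, ref_measurement("s", 1000, 50), Ai)
  q_biased <- qams_quantify(1, ref_measurement("s", 1050, 50), Ai)
  expect_equal(esm, 50)
  expect_equal(q_ok, 50)
  expect_equal(q_biased, 50 / 1.05, tolerance = 1e-10)
})

test_that("parameter recovery: known concentrations are recovered by ESM", {
  m <- ld5_method()
  pk <- ld5_measure(m, 50, seed = 123)
  mp <- match_peaks(pk, m)
  curves <- ld5_curves()
  for (i in seq_len(nrow(mp))) {
    found <- as.numeric(esm_quantify(curves[[mp$analyte[i]]], mp$area[i]))
    expect_equal(found, 50, tolerance = 0.03)  # 3 x the ~0.5 % area CV
  }
})

test_that("the validation report aggregates every block", {
  m <- ld5_method()
  rep <- run_validation(m, seed = 2, n_samples = 10)
  expect_s3_class(rep, "validation_report")
  expect_true(all(c("linearity", "precision", "stability", "recovery",
                    "robustness", "comparison") %in% names(rep)))
  expect_equal(nrow(rep$linearity), 5)
  expect_true(all(rep$linearity$r > 0.999))
  expect_true(all(rep$recovery$summary$mean_recovery_pct > 90))
})
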