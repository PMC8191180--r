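# ICH-style validation battery run end-to-end on simulated chromatograms:
# precision, stability, spike recovery, robustness (retention/RCF/resolution)
# and the external-standard vs single-marker comparison. Every operation
# renders chromatograms at the quantification wavelength, estimates the
# baseline, detects and integrates peaks, and quantifies from the measured
# areas; nothing is read off the generator's internal state except expected
# retention times for peak-to-analyte assignment.

#' Relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values At least 2 numbers with non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  qk_check(is.numeric(values) && length(values) >= 2,
           "need at least 2 values", "invalid_input")
  m <- mean(values)
  qk_check(m != 0, "RSD undefined for zero mean", "undefined_rsd")
  100 * stats::sd(values) / m
}

# Curves implied by a method's configured responses (range = the assay's
# calibrated 2.5-150 ug/mL span).
method_curves <- function(method) {
  out <- lapply(method$analytes, function(a) {
    new_calibration_curve(analyte = a$name, slope = a$response_slope,
                          intercept = a$response_intercept, r = NA_real_,
                          range_low = 2.5, range_high = 150)
  })
  stats::setNames(out, analyte_names(method))
}

# The common detection wavelength of a method (every packaged validation op
# quantifies at the wavelength the responses are calibrated at).
method_wavelength <- function(method) {
  wl <- unique(vapply(method$analytes, `[[`, numeric(1),
                      "detection_wavelength_nm"))
  qk_check(length(wl) == 1,
           "analytes must share one detection wavelength for batch measurement",
           "invalid_parameter")
  wl
}

# Render one injection and measure all analyte peaks at `wavelength`.
# Returns a data frame analyte/apex_min/area (NA where a peak was missed).
measure_injection <- function(method, conc, seed,
                              wavelength = method_wavelength(method)) {
  ch <- render_chromatogram(method, conc, seed = seed,
                            wavelengths = wavelength)
  tr <- get_trace(ch, wavelength)
  bl <- estimate_baseline(tr)
  pk <- detect_peaks(tr, baseline = bl)
  mp <- match_peaks(pk, method)
  data.frame(analyte = mp$analyte, apex_min = mp$apex_min, area = mp$area,
             stringsAsFactors = FALSE)
}

# n injections -> matrix of areas (rows = injections, cols = analytes) and
# matrix of apices. Seeds are drawn deterministically from `seed`.
measure_series <- function(method, conc, n, seed,
                           wavelength = method_wavelength(method)) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n))
  nms <- analyte_names(method)
  areas <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
  apices <- areas
  for (i in seq_len(n)) {
    m <- measure_injection(method, conc, seeds[i], wavelength)
    areas[i, m$analyte] <- m$area
    apices[i, m$analyte] <- m$apex_min
  }
  list(areas = areas, apices = apices)
}

#' Intraday and interday precision
#'
#' Simulates repeated injections of the mixed standard: `n_intra` injections
#' per day over `n_days` days. Within a day only detector noise varies;
#' between days an additional multiplicative day-level gain
#' `~ Normal(1, day_gain_sd)` models detector/injection drift. Reports the
#' RSD of peak areas per analyte, intraday (day 1) and interday (all runs).
#'
#' @param method An [instrument_method()].
#' @param conc Concentration of every analyte, ug/mL (or named vector).
#' @param n_intra Injections per day (>= 2).
#' @param n_days Days (>= 2).
#' @param day_gain_sd Day-level gain sd; default 0.01.
#' @param seed Seed.
#' @return Data frame `analyte`, `intraday_rsd_pct`, `interday_rsd_pct`.
#' @export
run_precision <- function(method, conc = 50, n_intra = 6, n_days = 6,
                          day_gain_sd = 0.01, seed = NULL) {
  qk_check(n_intra >= 2 && n_days >= 2,
           "need n_intra >= 2 and n_days >= 2", "invalid_parameter")
  gains <- with_seed(seed, stats::rnorm(n_days, 1, day_gain_sd))
  gains <- pmax(gains, 0.5)
  all_areas <- NULL
  for (d in seq_len(n_days)) {
    md <- perturb_method(method, condition_delta(gain_factor = gains[d]))
    day_seed <- if (is.null(seed)) NULL else seed + 1000 * d
    res <- measure_series(md, conc, n_intra, day_seed)
    all_areas <- rbind(all_areas, res$areas)
  }
  nms <- analyte_names(method)
  data.frame(
    analyte = nms,
    intraday_rsd_pct = vapply(nms, function(nm)
      rsd(all_areas[seq_len(n_intra), nm]), numeric(1)),
    interday_rsd_pct = vapply(nms, function(nm)
      rsd(all_areas[, nm]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Spike recovery
#'
#' Spikes a simulated sample solution with known amounts at several levels,
#' quantifies base and spiked solutions by the external-standard method, and
#' reports `recovery = 100 * (found_spiked - found_base) / added` per level
#' (each injected in triplicate) plus per-analyte mean and RSD.
#'
#' @param method An [instrument_method()].
#' @param base_conc Base sample concentration, ug/mL (all analytes).
#' @param spike_levels Added amounts, ug/mL.
#' @param n_rep Injections per solution (>= 1; the assay convention is 3).
#' @param curves Named list of `calibration_curve`s; defaults to the curves
#'   implied by the method's configured responses.
#' @param seed Seed.
#' @return List with `per_level` (analyte, spike, mean recovery) and
#'   `summary` (analyte, mean_recovery_pct, rsd_pct).
#' @export
run_recovery <- function(method, base_conc = 50, spike_levels = c(40, 50, 60),
                         n_rep = 3, curves = NULL, seed = NULL) {
  qk_check(all(spike_levels > 0), "spike levels must be > 0",
           "invalid_parameter")
  qk_check(n_rep >= 1, "n_rep must be >= 1", "invalid_parameter")
  if (is.null(curves)) curves <- method_curves(method)
  nms <- analyte_names(method)
  base <- measure_series(method, base_conc, n_rep,
                         if (is.null(seed)) NULL else seed + 1)
  found_base <- vapply(nms, function(nm)
    mean(esm_quantify(curves[[nm]], base$areas[, nm])), numeric(1))
  per_level <- NULL
  rec_all <- stats::setNames(vector("list", length(nms)), nms)
  for (k in seq_along(spike_levels)) {
    sp <- spike_levels[k]
    res <- measure_series(method, base_conc + sp, n_rep,
                          if (is.null(seed)) NULL else seed + 100 * (k + 1))
    for (nm in nms) {
      found <- suppressWarnings(esm_quantify(curves[[nm]], res$areas[, nm]))
      rec <- 100 * (found - found_base[[nm]]) / sp
      rec_all[[nm]] <- c(rec_all[[nm]], rec)
      per_level <- rbind(per_level,
                         data.frame(analyte = nm, spike = sp,
                                    recovery_pct = mean(rec),
                                    stringsAsFactors = FALSE))
    }
  }
  summary <- data.frame(
    analyte = nms,
    mean_recovery_pct = vapply(nms, function(nm) mean(rec_all[[nm]]),
                               numeric(1)),
    rsd_pct = vapply(nms, function(nm) rsd(rec_all[[nm]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_level = per_level, summary = summary)
}

#' Solution stability over time
#'
#' Simulates injections of the same solution at the given timepoints with an
#' optional first-order degradation `conc(t) = conc * exp(-rate * t)` and
#' reports the RSD of peak areas over the timepoints per analyte.
#'
#' @param method An [instrument_method()].
#' @param conc Concentration at time zero, ug/mL.
#' @param timepoints Hours; default 0, 1, 2, 4, 6, 8.
#' @param degradation_rate First-order decay rate per hour (>= 0).
#' @param seed Seed.
#' @return Data frame `analyte`, `rsd_pct`.
#' @export
run_stability <- function(method, conc = 50, timepoints = c(0, 1, 2, 4, 6, 8),
                          degradation_rate = 0, seed = NULL) {
  qk_check(length(timepoints) >= 2, "need at least 2 timepoints",
           "invalid_input")
  qk_check(degradation_rate >= 0, "degradation rate must be >= 0",
           "invalid_parameter")
  nms <- analyte_names(method)
  areas <- matrix(NA_real_, length(timepoints), length(nms),
                  dimnames = list(NULL, nms))
  for (i in seq_along(timepoints)) {
    ct <- conc * exp(-degradation_rate * timepoints[i])
    m <- measure_injection(method, ct,
                           if (is.null(seed)) NULL else seed + 17 * i)
    areas[i, m$analyte] <- m$area
  }
  data.frame(analyte = nms,
             rsd_pct = vapply(nms, function(nm) rsd(areas[, nm]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default robustness condition grid
#'
#' One-factor-at-a-time grid at the assay's stated magnitudes: mobile-phase
#' pH 3.8/4.0/4.2, flow 0.98/1.00/1.02 mL/min (+/-2 %), organic fraction
#' 34/36/38 % acetonitrile (+/-2 points), column temperature 29/30/31 C.
#'
#' @return Data frame with columns `factor`, `level` and the
#'   [condition_delta()] fields.
#' @export
default_condition_grid <- function() {
  rbind(
    data.frame(factor = "pH", level = c(3.8, 4.0, 4.2),
               d_pH = c(-0.2, 0, 0.2), d_flow_frac = 0, d_temp_C = 0,
               d_organic_frac = 0),
    data.frame(factor = "flow_rate", level = c(0.98, 1.0, 1.02),
               d_pH = 0, d_flow_frac = c(-0.02, 0, 0.02), d_temp_C = 0,
               d_organic_frac = 0),
    data.frame(factor = "organic_fraction", level = c(34, 36, 38),
               d_pH = 0, d_flow_frac = 0, d_temp_C = 0,
               d_organic_frac = c(-0.02, 0, 0.02)),
    data.frame(factor = "temperature", level = c(29, 30, 31),
               d_pH = 0, d_flow_frac = 0, d_temp_C = c(-1, 0, 1),
               d_organic_frac = 0)
  )
}

#' Robustness study: retention, RCF and resolution across conditions
#'
#' Renders the mixed standard under every condition of the grid (each in
#' `n_rep` replicate injections), detects and integrates peaks, and reports:
#' per-analyte relative-retention-time RSDs per factor (reference analyte
#' excluded, its RRT is 1 by definition) and the mean +/- 3 sd acceptance
#' band; pooled per-analyte RCF mean and RSD across all conditions (each
#' condition's RCF from replicate-mean areas); and the minimum resolution of
#' adjacent peak pairs over the grid. Conditions where fewer than the full
#' set of peaks is found are reported as failed and excluded.
#'
#' @param method An [instrument_method()].
#' @param grid Condition grid as from [default_condition_grid()].
#' @param conc Standard concentration, ug/mL.
#' @param n_rep Replicate injections per condition.
#' @param reference Internal reference analyte name.
#' @param seed Seed.
#' @return List with `rrt_rsd` (analyte x factor RSD table), `rrt_bands`
#'   (pooled mean, sd, mean +/- 3 sd), `rcf` (pooled mean RCF + RSD),
#'   `min_resolution`, `failed_conditions`.
#' @export
run_robustness <- function(method, grid = default_condition_grid(),
                           conc = 50, n_rep = 3,
                           reference = "etacrynic acid", seed = NULL) {
  qk_check(nrow(grid) >= 1, "grid must be non-empty", "invalid_input")
  nms <- analyte_names(method)
  qk_check(reference %in% nms, "reference analyte not in method",
           "missing_reference")
  n_analytes <- length(nms)
  cond_rows <- list()
  failed <- integer(0)
  for (g in seq_len(nrow(grid))) {
    delta <- condition_delta(d_pH = grid$d_pH[g],
                             d_flow_frac = grid$d_flow_frac[g],
                             d_temp_C = grid$d_temp_C[g],
                             d_organic_frac = grid$d_organic_frac[g])
    pm <- perturb_method(method, delta)
    res <- measure_series(pm, conc, n_rep,
                          if (is.null(seed)) NULL else seed + 31 * g)
    if (any(!is.finite(res$areas))) { failed <- c(failed, g); next }
    mean_area <- colMeans(res$areas)
    mean_apex <- colMeans(res$apices)
    t0 <- pm$dead_time_marker_retention_min
    tR <- mean_apex[[reference]]
    rrt <- vapply(nms, function(nm)
      relative_retention_time(mean_apex[[nm]], t0, tR, nm)$rrt, numeric(1))
    ref_m <- ref_measurement(reference, mean_area[[reference]], conc)
    rcf <- vapply(nms, function(nm)
      compute_rcf(ref_m, ref_measurement(nm, mean_area[[nm]], conc))$rcf,
      numeric(1))
    # minimum adjacent-pair resolution from one replicate's peak table
    wl <- method_wavelength(pm)
    pk1 <- detect_peaks(get_trace(render_chromatogram(
      pm, conc, seed = if (is.null(seed)) NULL else seed + 31 * g + 7,
      wavelengths = wl), wl))
    res_min <- if (nrow(pk1) >= 2) {
      min(vapply(seq_len(nrow(pk1) - 1), function(i)
        resolution(pk1[i, ], pk1[i + 1, ]), numeric(1)))
    } else NA_real_
    cond_rows[[length(cond_rows) + 1]] <-
      list(factor = grid$factor[g], rrt = rrt, rcf = rcf, res_min = res_min)
  }
  qk_check(length(cond_rows) >= 2, "fewer than 2 usable conditions",
           "incomplete_grid")
  factors <- vapply(cond_rows, `[[`, character(1), "factor")
  rrt_mat <- do.call(rbind, lapply(cond_rows, `[[`, "rrt"))
  rcf_mat <- do.call(rbind, lapply(cond_rows, `[[`, "rcf"))
  others <- setdiff(nms, reference)

  rrt_rsd <- do.call(rbind, lapply(unique(factors), function(f) {
    idx <- factors == f
    data.frame(factor = f, analyte = others,
               rsd_pct = vapply(others, function(nm) rsd(rrt_mat[idx, nm]),
                                numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rrt_bands <- data.frame(
    analyte = others,
    mean_rrt = vapply(others, function(nm) mean(rrt_mat[, nm]), numeric(1)),
    sd_rrt = vapply(others, function(nm) stats::sd(rrt_mat[, nm]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  rrt_bands$lower_3s <- rrt_bands$mean_rrt - 3 * rrt_bands$sd_rrt
  rrt_bands$upper_3s <- rrt_bands$mean_rrt + 3 * rrt_bands$sd_rrt

  rcf_tab <- data.frame(
    analyte = others,
    mean_rcf = vapply(others, function(nm) mean(rcf_mat[, nm]), numeric(1)),
    rsd_pct = vapply(others, function(nm) rsd(rcf_mat[, nm]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  list(rrt_rsd = rrt_rsd, rrt_bands = rrt_bands, rcf = rcf_tab,
       min_resolution = min(vapply(cond_rows, `[[`, numeric(1), "res_min"),
                            na.rm = TRUE),
       failed_conditions = failed)
}

#' Column-geometry surrogate for retention robustness
#'
#' Emulates switching between chromatographic columns of different
#' manufacture: each "column" rescales every analyte's retention time by an
#' independent log-normal factor, so relative retention times are no longer
#' preserved. Returns per-analyte RRT RSDs across the columns, computed
#' directly from the rescaled retention times. Contrast with
#' [run_robustness()], whose within-column condition changes shift all
#' retentions together and leave RRT nearly invariant.
#'
#' @param method An [instrument_method()].
#' @param n_columns Number of columns (>= 2).
#' @param log_sd Standard deviation of the per-analyte log retention factor;
#'   default 0.15.
#' @param reference Internal reference analyte name.
#' @param seed Seed.
#' @return Data frame `analyte`, `rsd_pct` (reference excluded).
#' @export
run_column_surrogate <- function(method, n_columns = 3, log_sd = 0.15,
                                 reference = "etacrynic acid", seed = NULL) {
  qk_check(n_columns >= 2, "need at least 2 columns", "invalid_parameter")
  nms <- analyte_names(method)
  qk_check(reference %in% nms, "reference analyte not in method",
           "missing_reference")
  rts <- vapply(method$analytes, `[[`, numeric(1), "retention_min")
  t0 <- method$dead_time_marker_retention_min
  fac <- with_seed(seed,
    matrix(exp(stats::rnorm(n_columns * length(nms), 0, log_sd)),
           n_columns, length(nms), dimnames = list(NULL, nms)))
  rrt <- t(apply(fac, 1, function(f) {
    rt <- rts * f
    (rt - t0) / (rt[[reference]] - t0)
  }))
  others <- setdiff(nms, reference)
  data.frame(analyte = others,
             rsd_pct = vapply(others, function(nm) rsd(rrt[, nm]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare external-standard and single-marker quantification
#'
#' Simulates replicate mixed samples, quantifies every analyte both by the
#' external-standard method (per-analyte curve) and by the single-marker
#' method (reference concentration from its own curve, other analytes via
#' Eq.-style back-calculation with relative correction factors established
#' from replicate standard injections), and reports per-analyte accuracy and
#' RSD for both modes plus the dispersion of the per-sample relative
#' difference between modes.
#'
#' @param method An [instrument_method()].
#' @param sample_conc Nominal sample concentration, ug/mL (all analytes).
#' @param n_samples Number of simulated samples (>= 3).
#' @param n_cal_rep Replicate standard injections used to establish the RCFs.
#' @param reference Internal reference analyte name.
#' @param curves Calibration curves; default from the method's responses.
#' @param seed Seed.
#' @return List with `rcf` (established RCFs), `per_analyte` (accuracy % and
#'   RSD % per mode, and `rel_diff_sd_pct`: sd of the per-sample percent
#'   difference 100*(QAMS-ESM)/mean, reference excluded), and
#'   `max_rel_diff_sd_pct`.
#' @export
compare_esm_qams <- function(method, sample_conc = 50, n_samples = 200,
                             n_cal_rep = 3, reference = "etacrynic acid",
                             curves = NULL, seed = NULL) {
  qk_check(n_samples >= 3, "need at least 3 samples", "invalid_parameter")
  nms <- analyte_names(method)
  qk_check(reference %in% nms, "reference analyte not in method",
           "missing_reference")
  if (is.null(curves)) curves <- method_curves(method)
  # establish RCFs from replicate mixed-standard injections at 50 ug/mL
  cal <- measure_series(method, 50, n_cal_rep,
                        if (is.null(seed)) NULL else seed + 5)
  cal_mean <- colMeans(cal$areas)
  qk_check(all(is.finite(cal_mean)), "calibration injection lost a peak",
           "incomplete_grid")
  ref_m <- ref_measurement(reference, cal_mean[[reference]], 50)
  rcfs <- vapply(nms, function(nm)
    compute_rcf(ref_m, ref_measurement(nm, cal_mean[[nm]], 50))$rcf,
    numeric(1))
  # simulate and quantify samples
  smp <- measure_series(method, sample_conc, n_samples,
                        if (is.null(seed)) NULL else seed + 9)
  esm <- matrix(NA_real_, n_samples, length(nms), dimnames = list(NULL, nms))
  qams <- esm
  for (i in seq_len(n_samples)) {
    As <- smp$areas[i, reference]
    Cs <- esm_quantify(curves[[reference]], As)
    run_ref <- ref_measurement(reference, As, as.numeric(Cs))
    for (nm in nms) {
      esm[i, nm] <- esm_quantify(curves[[nm]], smp$areas[i, nm])
      qams[i, nm] <- qams_quantify(rcfs[[nm]], run_ref, smp$areas[i, nm])
    }
  }
  others <- setdiff(nms, reference)
  rel_diff <- 100 * (qams[, others, drop = FALSE] -
                       esm[, others, drop = FALSE]) /
    ((qams[, others, drop = FALSE] + esm[, others, drop = FALSE]) / 2)
  per_analyte <- data.frame(
    analyte = nms,
    esm_accuracy_pct = 100 * colMeans(esm) / sample_conc,
    esm_rsd_pct = apply(esm, 2, rsd),
    qams_accuracy_pct = 100 * colMeans(qams) / sample_conc,
    qams_rsd_pct = apply(qams, 2, rsd),
    rel_diff_sd_pct = vapply(nms, function(nm)
      if (nm %in% others) stats::sd(rel_diff[, nm]) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(rcf = data.frame(analyte = nms, rcf = unname(rcfs),
                        stringsAsFactors = FALSE),
       per_analyte = per_analyte,
       max_rel_diff_sd_pct = max(per_analyte$rel_diff_sd_pct, na.rm = TRUE))
}

#' Run the full validation battery
#'
#' Executes linearity (+ detection limits), precision, stability, recovery,
#' robustness and the method comparison on the given method and collects the
#' results into a `validation_report`.
#'
#' @param method An [instrument_method()].
#' @param seed Seed governing every stochastic block.
#' @param n_samples Samples for the method comparison.
#' @param blocks Character vector selecting blocks (default all of
#'   `"linearity"`, `"precision"`, `"stability"`, `"recovery"`,
#'   `"robustness"`, `"comparison"`).
#' @return An object of class `validation_report` (a named list of block
#'   results plus the seed).
#' @export
run_validation <- function(method, seed = 1, n_samples = 200,
                           blocks = c("linearity", "precision", "stability",
                                      "recovery", "robustness",
                                      "comparison")) {
  rep <- list(seed = seed)
  if ("linearity" %in% blocks) {
    pts <- simulate_calibration_areas(method, area_cv = 0.01, seed = seed + 11)
    rep$linearity <- do.call(rbind, lapply(split(pts, pts$analyte),
                                           function(d) {
      cv <- fit_calibration(d, analyte = d$analyte[1])
      a <- method$analytes[[d$analyte[1]]]
      data.frame(analyte = cv$analyte, slope = cv$slope,
                 intercept = cv$intercept, r = cv$r,
                 range_low = cv$range_low, range_high = cv$range_high,
                 lod = if (is.finite(a$lod_area_sd))
                   lod(cv, a$lod_area_sd) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(rep$linearity) <- NULL
  }
  if ("precision" %in% blocks)
    rep$precision <- run_precision(method, seed = seed + 23)
  if ("stability" %in% blocks)
    rep$stability <- run_stability(method, seed = seed + 29)
  if ("recovery" %in% blocks)
    rep$recovery <- run_recovery(method, seed = seed + 7)
  if ("robustness" %in% blocks)
    rep$robustness <- run_robustness(method, seed = seed + 13)
  if ("comparison" %in% blocks)
    rep$comparison <- compare_esm_qams(method, n_samples = n_samples,
                                       seed = seed + 42)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> seed %s; blocks: %s\n",
              format(x$seed),
              paste(setdiff(names(x), "seed"), collapse = ", ")))
  if (!is.null(x$comparison))
    cat(sprintf("  max between-mode relative-difference sd: %.2f %%\n",
                x$comparison$max_rel_diff_sd_pct))
  if (!is.null(x$robustness))
    cat(sprintf("  max RRT RSD %.2f %%, max RCF RSD %.2f %%, min Rs %.2f\n",
                max(x$robustness$rrt_rsd$rsd_pct),
                max(x$robustness$rcf$rsd_pct), x$robustness$min_resolution))
  invisible(x)
}
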