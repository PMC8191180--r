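# File formats: chromatogram CSV (header time_min,<w1>,<w2>,... with integer
# nm), peak/calibration/RCF tables, method configuration (YAML or JSON) and
# the validation report bundle. Number formatting mirrors the assay's table
# precision (4 decimals for RCF/similarity, 1 for RSD/recovery percentages)
# so reports diff cleanly.

fmt_sig <- function(x, digits = 9) {
  formatC(x, digits = digits, format = "g", width = 1)
}

#' Write a chromatogram to CSV
#'
#' UTF-8, comma-separated, header `time_min,<w1>,<w2>,...` with integer
#' wavelengths, rows ascending in time, absorbance with 9 significant digits.
#'
#' @param chrom A `chromatogram`.
#' @param path Output file.
#' @param digits Significant digits for absorbance (default 9).
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path, digits = 9) {
  qk_check(inherits(chrom, "chromatogram"), "chrom must be a chromatogram",
           "invalid_input")
  wl <- chrom$wavelength_nm
  qk_check(all(abs(wl - round(wl)) < 1e-9),
           "chromatogram wavelengths must be integer nm for the CSV dialect",
           "format_error")
  header <- paste(c("time_min", format(as.integer(round(wl)),
                                       trim = TRUE, scientific = FALSE)),
                  collapse = ",")
  body <- cbind(fmt_sig(chrom$time_min, digits),
                matrix(fmt_sig(chrom$absorbance, digits),
                       nrow = nrow(chrom$absorbance)))
  lines <- c(header, apply(body, 1, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a chromatogram from CSV
#'
#' Parses the dialect written by [write_chromatogram()], validating the
#' header, numeric fields, row shape and ascending time; malformed input
#' raises a format error naming the offending line.
#'
#' @param path CSV file.
#' @return A `chromatogram`.
#' @export
read_chromatogram <- function(path) {
  qk_check(file.exists(path), sprintf("file not found: %s", path),
           "format_error")
  lines <- readLines(path, warn = FALSE)
  qk_check(length(lines) >= 2, "file has no data rows", "format_error")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  qk_check(identical(header[1], "time_min"),
           "line 1: header must start with 'time_min'", "format_error")
  wl <- suppressWarnings(as.numeric(header[-1]))
  qk_check(length(wl) >= 1 && all(is.finite(wl)),
           "line 1: wavelength columns must be numeric", "format_error")
  qk_check(all(diff(wl) > 0), "line 1: wavelengths must be ascending",
           "format_error")
  ncol_expect <- length(header)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  for (i in seq_along(rows)) {
    qk_check(length(rows[[i]]) == ncol_expect,
             sprintf("line %d: expected %d fields, found %d", i + 1,
                     ncol_expect, length(rows[[i]])), "format_error")
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncol_expect)))
  bad <- which(colSums(!is.finite(vals)) > 0)
  qk_check(length(bad) == 0,
           sprintf("line %d: non-numeric value",
                   if (length(bad)) bad[1] + 1 else 0L), "format_error")
  vals <- t(vals)
  tm <- vals[, 1]
  qk_check(all(diff(tm) > 0), "time column must be strictly ascending",
           "format_error")
  structure(list(time_min = tm, wavelength_nm = wl,
                 absorbance = vals[, -1, drop = FALSE]),
            class = "chromatogram")
}

#' Write / read a peak table CSV
#'
#' Columns `analyte,wavelength_nm,apex_min,start_min,end_min,height_mAU,area`.
#'
#' @param peaks A `peak_table` (optionally with an `analyte` column).
#' @param path CSV file.
#' @return `path` (write) / a `peak_table` data frame (read).
#' @export
write_peak_table <- function(peaks, path) {
  df <- as.data.frame(peaks)
  if (is.null(df$analyte)) df$analyte <- NA_character_
  df <- df[, c("analyte", "wavelength_nm", "apex_min", "start_min",
               "end_min", "height_mAU", "area")]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  qk_check(file.exists(path), sprintf("file not found: %s", path),
           "format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "wavelength_nm", "apex_min", "start_min", "end_min",
            "height_mAU", "area")
  qk_check(all(need %in% names(df)),
           paste("peak table missing column(s):",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "format_error")
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read a calibration point table
#'
#' CSV with columns `analyte,concentration_ug_ml,area`.
#'
#' @param path CSV file.
#' @return Data frame with `analyte`, `concentration`, `area`.
#' @export
read_calibration_table <- function(path) {
  qk_check(file.exists(path), sprintf("file not found: %s", path),
           "format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "concentration_ug_ml", "area")
  qk_check(all(need %in% names(df)),
           paste("calibration table missing column(s):",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "format_error")
  data.frame(analyte = df$analyte, concentration = df$concentration_ug_ml,
             area = df$area, stringsAsFactors = FALSE)
}

#' Write / read fitted calibration curves
#'
#' CSV with columns `analyte,slope,intercept,r,range_low,range_high,lod`.
#'
#' @param curves Named list of `calibration_curve` objects.
#' @param path CSV file.
#' @return `path` (write) / named list of curves (read).
#' @export
write_calibration_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(analyte = cv$analyte, slope = cv$slope,
               intercept = cv$intercept, r = cv$r, range_low = cv$range_low,
               range_high = cv$range_high, lod = cv$lod,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_calibration_curves
#' @export
read_calibration_curves <- function(path) {
  qk_check(file.exists(path), sprintf("file not found: %s", path),
           "format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "slope", "intercept", "r", "range_low", "range_high")
  qk_check(all(need %in% names(df)),
           paste("curves file missing column(s):",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "format_error")
  if (is.null(df$lod)) df$lod <- NA_real_
  out <- lapply(seq_len(nrow(df)), function(i)
    new_calibration_curve(df$analyte[i], df$slope[i], df$intercept[i],
                          df$r[i], df$range_low[i], df$range_high[i],
                          df$lod[i]))
  stats::setNames(out, df$analyte)
}

#' Write / read a relative-correction-factor table
#'
#' CSV with columns `analyte,wavelength_nm,rsd_pct,rcf`; the RCF is printed
#' with 4 decimals and the RSD with 1 (the assay's table precision).
#'
#' @param rcf_table Data frame with those columns (see [ld5_rcf_table()]).
#' @param path CSV file.
#' @return `path` (write) / data frame (read).
#' @export
write_rcf_table <- function(rcf_table, path) {
  df <- data.frame(analyte = rcf_table$analyte,
                   wavelength_nm = rcf_table$wavelength_nm,
                   rsd_pct = ifelse(is.na(rcf_table$rsd_pct), "",
                                    sprintf("%.1f", rcf_table$rsd_pct)),
                   rcf = sprintf("%.4f", rcf_table$rcf),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_rcf_table
#' @export
read_rcf_table <- function(path) {
  qk_check(file.exists(path), sprintf("file not found: %s", path),
           "format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "rcf")
  qk_check(all(need %in% names(df)),
           paste("RCF table missing column(s):",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "format_error")
  df$rcf <- as.numeric(df$rcf)
  df
}

#' Read / write an instrument method configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) with keys mirroring
#' [instrument_method()] and [analyte_spec()] field names; `time_grid` is a
#' mapping with `start`, `end`, `step`.
#'
#' @param path Configuration file.
#' @return An `instrument_method` (read); `path` invisibly (write).
#' @export
read_method_config <- function(path) {
  qk_check(file.exists(path), sprintf("file not found: %s", path),
           "format_error")
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    qk_stop("config must be .yaml/.yml or .json", "format_error")
  }
  qk_check(is.list(cfg) && !is.null(cfg$analytes),
           "config must define analytes", "format_error")
  to_analyte <- function(a) {
    qk_check(!is.null(a$uv_spectrum), "analyte config needs uv_spectrum",
             "format_error")
    analyte_spec(
      name = a$name, retention_min = a$retention_min,
      sigma_min = a$sigma_min,
      uv_spectrum = uv_spectrum(unlist(a$uv_spectrum$wavelengths_nm),
                                unlist(a$uv_spectrum$absorbance)),
      response_slope = a$response_slope,
      response_intercept = a$response_intercept %||% 0,
      detection_wavelength_nm = a$detection_wavelength_nm %||% 278,
      qams_wavelength_nm = a$qams_wavelength_nm %||%
        (a$detection_wavelength_nm %||% 278))
  }
  analytes <- if (is.data.frame(cfg$analytes)) {
    # jsonlite may simplify to a data frame; rebuild row lists
    lapply(seq_len(nrow(cfg$analytes)), function(i)
      to_analyte(lapply(cfg$analytes, function(col)
        if (is.list(col)) col[[i]] else col[i])))
  } else {
    lapply(cfg$analytes, to_analyte)
  }
  tg <- cfg$time_grid %||% list()
  instrument_method(
    analytes,
    dead_time_marker_retention_min = cfg$dead_time_marker_retention_min %||% 1.5,
    time_start = tg$start %||% 0, time_end = tg$end %||% 25,
    time_step = tg$step %||% 0.005,
    wavelength_grid_nm = unlist(cfg$wavelength_grid_nm %||% 230:360),
    baseline_level = cfg$baseline_level %||% 2,
    baseline_drift_per_min = cfg$baseline_drift_per_min %||% 0.05,
    noise_sd = cfg$noise_sd %||% 0, seed = cfg$seed)
}

#' @rdname read_method_config
#' @param method An `instrument_method` to serialise.
#' @export
write_method_config <- function(method, path) {
  qk_check(inherits(method, "instrument_method"),
           "method must be an instrument_method", "invalid_input")
  cfg <- list(
    analytes = lapply(unname(method$analytes), function(a)
      list(name = a$name, retention_min = a$retention_min,
           sigma_min = a$sigma_min,
           uv_spectrum = list(wavelengths_nm = a$uv_spectrum$wavelengths_nm,
                              absorbance = a$uv_spectrum$absorbance),
           response_slope = a$response_slope,
           response_intercept = a$response_intercept,
           detection_wavelength_nm = a$detection_wavelength_nm,
           qams_wavelength_nm = a$qams_wavelength_nm)),
    dead_time_marker_retention_min = method$dead_time_marker_retention_min,
    time_grid = list(start = method$time_start, end = method$time_end,
                     step = method$time_step),
    wavelength_grid_nm = method$wavelength_grid_nm,
    baseline_level = method$baseline_level,
    baseline_drift_per_min = method$baseline_drift_per_min,
    noise_sd = method$noise_sd, seed = method$seed)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(cfg, path, precision = 12)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    qk_stop("config must be .yaml/.yml or .json", "format_error")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt1 <- function(x) ifelse(is.na(x), NA, sprintf("%.1f", x))
fmt4 <- function(x) ifelse(is.na(x), NA, sprintf("%.4f", x))

#' Write a validation report bundle
#'
#' Serialises a `validation_report` (see [run_validation()]) into a JSON
#' summary plus one CSV per block, with deterministic column order and the
#' assay's table precision (4 decimals for RCF, 1 for RSD/recovery
#' percentages). Re-running with the same seed reproduces byte-identical
#' files.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  qk_check(inherits(report, "validation_report"),
           "report must be a validation_report", "invalid_input")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  qk_check(ok && dir.exists(dir), sprintf("cannot create directory %s", dir),
           "io_error")
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    files <<- c(files, p)
  }
  if (!is.null(report$linearity)) {
    d <- report$linearity
    d$slope <- fmt4(d$slope); d$intercept <- fmt4(d$intercept)
    d$r <- fmt4(d$r); d$lod <- fmt4(d$lod)
    put(d[, c("analyte", "slope", "intercept", "r", "range_low",
              "range_high", "lod")], "linearity.csv")
  }
  if (!is.null(report$precision)) {
    d <- report$precision
    d$intraday_rsd_pct <- fmt1(d$intraday_rsd_pct)
    d$interday_rsd_pct <- fmt1(d$interday_rsd_pct)
    put(d, "precision.csv")
  }
  if (!is.null(report$stability)) {
    d <- report$stability
    d$rsd_pct <- fmt1(d$rsd_pct)
    put(d, "stability.csv")
  }
  if (!is.null(report$recovery)) {
    d <- report$recovery$summary
    d$mean_recovery_pct <- fmt1(d$mean_recovery_pct)
    d$rsd_pct <- fmt1(d$rsd_pct)
    put(d, "recovery.csv")
  }
  if (!is.null(report$robustness)) {
    d <- report$robustness$rcf
    d$mean_rcf <- fmt4(d$mean_rcf); d$rsd_pct <- fmt1(d$rsd_pct)
    put(d, "robustness_rcf.csv")
    d2 <- report$robustness$rrt_rsd
    d2$rsd_pct <- fmt1(d2$rsd_pct)
    put(d2, "robustness_rrt.csv")
  }
  if (!is.null(report$comparison)) {
    d <- report$comparison$per_analyte
    for (cc in c("esm_accuracy_pct", "esm_rsd_pct", "qams_accuracy_pct",
                 "qams_rsd_pct", "rel_diff_sd_pct")) d[[cc]] <- fmt1(d[[cc]])
    put(d, "comparison.csv")
  }
  summary <- list(seed = report$seed)
  if (!is.null(report$comparison))
    summary$max_rel_diff_sd_pct <- report$comparison$max_rel_diff_sd_pct
  if (!is.null(report$robustness)) {
    summary$max_rrt_rsd_pct <- max(report$robustness$rrt_rsd$rsd_pct)
    summary$max_rcf_rsd_pct <- max(report$robustness$rcf$rsd_pct)
    summary$min_resolution <- report$robustness$min_resolution
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = 8)
  files <- c(files, p)
  invisible(files)
}
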