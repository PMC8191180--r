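# Single-wavelength trace processing: baseline estimation, peak detection with
# parabolic apex refinement, trapezoidal integration, resolution and S/N.

#' Single-wavelength absorbance trace
#'
#' @param time_min Strictly ascending time grid, minutes (length >= 3).
#' @param absorbance_mAU Absorbance values, mAU, same length.
#' @param wavelength_nm Wavelength of the trace, nm.
#' @return An object of class `trace`.
#' @export
trace <- function(time_min, absorbance_mAU, wavelength_nm = NA_real_) {
  qk_check(is.numeric(time_min) && is.numeric(absorbance_mAU),
           "trace grids must be numeric", "invalid_input")
  qk_check(length(time_min) == length(absorbance_mAU),
           "time and absorbance grids must have equal length", "invalid_input")
  qk_check(length(time_min) >= 3, "a trace needs at least 3 points",
           "invalid_input")
  qk_check(all(diff(time_min) > 0), "time must be strictly ascending",
           "invalid_input")
  structure(list(time_min = as.numeric(time_min),
                 absorbance_mAU = as.numeric(absorbance_mAU),
                 wavelength_nm = wavelength_nm),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %g nm, %d points, %g-%g min\n", x$wavelength_nm,
              length(x$time_min), min(x$time_min), max(x$time_min)))
  invisible(x)
}

#' Extract a single-wavelength trace from a chromatogram
#'
#' @param chrom A `chromatogram` (see [render_chromatogram()]).
#' @param wavelength_nm Wavelength to extract; must be on the chromatogram's
#'   grid (within 1e-6 nm).
#' @return A [trace()].
#' @export
get_trace <- function(chrom, wavelength_nm) {
  qk_check(inherits(chrom, "chromatogram"), "chrom must be a chromatogram",
           "invalid_input")
  i <- which(abs(chrom$wavelength_nm - wavelength_nm) < 1e-6)
  qk_check(length(i) == 1,
           sprintf("wavelength %g nm is not on the chromatogram grid",
                   wavelength_nm), "invalid_input")
  trace(chrom$time_min, chrom$absorbance[, i], chrom$wavelength_nm[i])
}

#' Estimate the baseline of a trace
#'
#' Asymmetrically reweighted penalized least squares (Whittaker smoothing with
#' a second-difference penalty): peak regions are progressively down-weighted
#' while noise-only regions keep near-symmetric weights, so the estimate is
#' unbiased under i.i.d. noise and reproduces constant and linear baselines
#' exactly (lines lie in the penalty's null space).
#'
#' @param trace A [trace()] with at least 10 points.
#' @param smooth_min Characteristic smoothing length in minutes; features
#'   narrower than this are treated as peaks. Default 1.5 min (wider than the
#'   broadest packaged peak).
#' @param maxit Maximum reweighting iterations.
#' @return A [trace()] on the same grid holding the baseline.
#' @export
estimate_baseline <- function(trace, smooth_min = 1.5, maxit = 20) {
  qk_check(inherits(trace, "trace"), "trace must be a trace object",
           "invalid_input")
  y <- trace$absorbance_mAU
  n <- length(y)
  qk_check(n >= 10, "trace is shorter than the smoothing window",
           "invalid_input")
  step <- mean(diff(trace$time_min))
  lambda <- (smooth_min / step)^4
  DtD <- penalty_matrix(n, lambda)
  # Work on the residual from a straight-line fit: lines span the penalty's
  # null space, so this leaves the solution unchanged while making constant
  # and purely linear baselines numerically exact.
  tt <- trace$time_min - mean(trace$time_min)
  slope0 <- sum(tt * y) / sum(tt^2)
  line <- mean(y) + slope0 * tt
  y <- y - line
  w <- rep(1, n)
  z <- y
  scale <- max(abs(y)) + 1e-12
  for (it in seq_len(maxit)) {
    A <- Matrix::forceSymmetric(Matrix::Diagonal(n, w) + DtD)
    ch <- Matrix::Cholesky(A, LDL = FALSE)
    z_new <- as.numeric(Matrix::solve(ch, w * y))
    # one step of iterative refinement: the penalty is ill-conditioned and a
    # raw solve leaves ~1e-8 relative error on an exact (constant) baseline
    resid <- w * y - as.numeric(A %*% z_new)
    z_new <- z_new + as.numeric(Matrix::solve(ch, resid))
    conv <- max(abs(z_new - z)) < 1e-9 * scale
    z <- z_new
    d <- y - z
    if (max(abs(d)) < 1e-9 * scale) break  # trace is already all baseline
    dn <- d[d < 0]
    if (length(dn) < 2 || stats::sd(dn) < 1e-10 * scale) {
      # effectively noiseless: keep full weight below the fit, drop above
      wt <- as.numeric(d <= 1e-9 * scale)
      wt[wt == 0] <- 1e-6
    } else {
      m <- mean(dn); s <- stats::sd(dn)
      wt <- 1 / (1 + exp(pmin(2 * (d - (2 * s - m)) / s, 35)))
    }
    wt <- pmax(wt, 1e-6)  # keep the system positive definite
    if (conv || max(abs(wt - w)) < 1e-3) break
    w <- wt
  }
  trace(trace$time_min, z + line, trace$wavelength_nm)
}

# Second-difference penalty lambda * t(D) %*% D, cached per (n, lambda):
# baseline estimation is called once per rendered injection in the validation
# battery and the penalty never changes within a study.
penalty_cache <- new.env(parent = emptyenv())
penalty_matrix <- function(n, lambda) {
  key <- sprintf("%d_%.6g", n, lambda)
  if (!is.null(penalty_cache[[key]])) return(penalty_cache[[key]])
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  val <- Matrix::crossprod(D) * lambda
  penalty_cache[[key]] <- val
  val
}

# Moving-average smoother used only for peak picking (odd window, edges by
# shrinking window).
smooth_ma <- function(y, k) {
  if (k <= 1) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  h <- (k - 1) %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Robust noise estimate from first differences.
estimate_noise_sd <- function(y) stats::mad(diff(y)) / sqrt(2)

#' Detect peaks in a trace
#'
#' Finds local maxima of the baseline-corrected (and, for picking only,
#' lightly smoothed) signal above a height threshold; refines each apex by
#' 3-point parabolic interpolation; sets integration bounds at the nearer of
#' the adjacent valley and apex +/- 4 sigma-hat, where sigma-hat comes from
#' the full width at half height; and integrates each peak trapezoidally.
#'
#' @param trace A [trace()].
#' @param min_height_mAU Detection threshold on baseline-corrected height
#'   (>= 0). Default: 10 x the estimated noise sd, with a floor of 0.5 % of
#'   the tallest corrected signal.
#' @param baseline Optional baseline [trace()]; estimated if missing.
#' @param smooth_window Odd number of samples for the picking smoother;
#'   default approximately 0.08 min.
#' @param min_separation_min Peaks closer than this are merged (tallest kept).
#' @return A data frame of class `peak_table` with columns `apex_min`,
#'   `start_min`, `end_min`, `height_mAU`, `area`, `wavelength_nm`, sorted by
#'   apex time.
#' @export
detect_peaks <- function(trace, min_height_mAU = NULL, baseline = NULL,
                         smooth_window = NULL, min_separation_min = 0.2) {
  qk_check(inherits(trace, "trace"), "trace must be a trace object",
           "invalid_input")
  t <- trace$time_min
  n <- length(t)
  qk_check(n >= 5, "trace too short for peak detection", "invalid_input")
  step <- mean(diff(t))
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  y <- trace$absorbance_mAU - baseline$absorbance_mAU
  if (is.null(smooth_window)) {
    smooth_window <- max(5L, as.integer(round(0.08 / step)))
    if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1L
  }
  ys <- smooth_ma(y, smooth_window)
  noise <- estimate_noise_sd(y)
  if (is.null(min_height_mAU)) {
    min_height_mAU <- max(10 * noise, 0.005 * max(ys), 0)
  }
  qk_check(min_height_mAU >= 0, "threshold must be >= 0", "invalid_parameter")

  cand <- which(ys[2:(n - 1)] > ys[1:(n - 2)] &
                  ys[2:(n - 1)] >= ys[3:n]) + 1L
  cand <- cand[ys[cand] >= min_height_mAU]
  if (length(cand) == 0) {
    return(empty_peak_table(trace$wavelength_nm))
  }
  # Accept candidates tallest-first; a candidate is a genuine separate peak
  # only if the signal dips materially between it and every already-accepted
  # peak (valley-prominence criterion) and it is not within the hard merge
  # window. Noise wiggles riding on a broad peak's top fail the dip test.
  noise_s <- noise / sqrt(smooth_window)
  min_dip <- function(h) max(5 * noise_s, 0.02 * h)
  ord <- cand[order(ys[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in keep) {
      if (abs(t[i] - t[k]) < min_separation_min) { dup <- TRUE; break }
      rng <- if (k < i) ys[k:i] else ys[i:k]
      if (ys[i] - min(rng) < min_dip(ys[i])) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  keep <- sort(keep)

  peaks <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    # parabolic apex refinement on the smoothed signal
    delta <- 0
    if (i > 1 && i < n) {
      den <- ys[i - 1] - 2 * ys[i] + ys[i + 1]
      if (den < 0) delta <- 0.5 * (ys[i - 1] - ys[i + 1]) / den
      if (!is.finite(delta) || abs(delta) > 1) delta <- 0
    }
    apex <- t[i] + delta * step
    height <- y[i]
    # sigma-hat from full width at half height of the smoothed peak
    half <- ys[i] / 2
    il <- i; while (il > 1 && ys[il] > half) il <- il - 1
    ir <- i; while (ir < n && ys[ir] > half) ir <- ir + 1
    tl <- if (ys[il] <= half && il < i)
      stats::approx(ys[il:(il + 1)], t[il:(il + 1)], xout = half)$y else t[il]
    tr_ <- if (ys[ir] <= half && ir > i)
      stats::approx(ys[(ir - 1):ir], t[(ir - 1):ir], xout = half)$y else t[ir]
    sigma_hat <- max((tr_ - tl) / 2.3548, step)
    # valleys to adjacent kept peaks (or trace ends)
    prev <- if (j > 1) keep[j - 1] else 1L
    nxt <- if (j < length(keep)) keep[j + 1] else n
    vl <- if (prev < i) prev - 1L + which.min(ys[prev:i]) else 1L
    vr <- if (nxt > i) i - 1L + which.min(ys[i:nxt]) else n
    start <- max(t[vl], apex - 4 * sigma_hat, t[1])
    end <- min(t[vr], apex + 4 * sigma_hat, t[n])
    area <- trapezoid_area(t, y, start, end)
    data.frame(apex_min = apex, start_min = start, end_min = end,
               height_mAU = height, area = max(area, 0),
               wavelength_nm = trace$wavelength_nm)
  })
  out <- do.call(rbind, peaks)
  out <- out[order(out$apex_min), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

empty_peak_table <- function(wavelength_nm = NA_real_) {
  out <- data.frame(apex_min = numeric(0), start_min = numeric(0),
                    end_min = numeric(0), height_mAU = numeric(0),
                    area = numeric(0), wavelength_nm = numeric(0))
  class(out) <- c("peak_table", "data.frame")
  out
}

# Trapezoidal integral of (t, y) restricted to [start, end], with linear
# interpolation at the cut points.
trapezoid_area <- function(t, y, start, end) {
  if (end <= start) return(0)
  inside <- t > start & t < end
  tt <- c(start, t[inside], end)
  yy <- c(stats::approx(t, y, xout = start)$y, y[inside],
          stats::approx(t, y, xout = end)$y)
  pracma::trapz(tt, yy)
}

#' Integrate a peak
#'
#' Trapezoidal area of the baseline-corrected signal between the peak's
#' bounds. Negative numerical results (possible on pure noise) are clamped to
#' zero.
#'
#' @param trace A [trace()].
#' @param peak One peak: a single row of a `peak_table` (or any list with
#'   `start_min` and `end_min`).
#' @param baseline Optional baseline [trace()]; estimated if missing.
#' @return Peak area in mAU.min (>= 0).
#' @export
integrate_peak <- function(trace, peak, baseline = NULL) {
  qk_check(inherits(trace, "trace"), "trace must be a trace object",
           "invalid_input")
  start <- peak$start_min; end <- peak$end_min
  qk_check(is.numeric(start) && is.numeric(end) && length(start) == 1 &&
             length(end) == 1, "peak must carry scalar bounds", "invalid_input")
  qk_check(start >= trace$time_min[1] - 1e-9 &&
             end <= trace$time_min[length(trace$time_min)] + 1e-9 &&
             start < end,
           "peak bounds outside the trace grid", "invalid_input")
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  y <- trace$absorbance_mAU - baseline$absorbance_mAU
  max(trapezoid_area(trace$time_min, y, start, end), 0)
}

#' Chromatographic resolution between two peaks
#'
#' `Rs = 2 (apex2 - apex1) / (w1 + w2)` with base widths `w = end - start`.
#' Identical apices give 0; zero total width with distinct apices gives `Inf`.
#'
#' @param p1,p2 Peaks (rows of a `peak_table`), `p1` eluting first.
#' @return Unitless resolution.
#' @export
resolution <- function(p1, p2) {
  qk_check(p1$apex_min <= p2$apex_min, "p1 must elute before p2",
           "invalid_input")
  dt <- p2$apex_min - p1$apex_min
  if (dt == 0) return(0)
  w <- (p1$end_min - p1$start_min) + (p2$end_min - p2$start_min)
  if (w <= 0) return(Inf)
  2 * dt / w
}

#' Peak signal-to-noise ratio
#'
#' @param peak A peak (row of a `peak_table`).
#' @param noise_sd_mAU Baseline noise standard deviation, mAU (> 0).
#' @return `height / noise_sd`.
#' @export
signal_to_noise <- function(peak, noise_sd_mAU) {
  qk_check(is.numeric(noise_sd_mAU) && noise_sd_mAU > 0,
           "noise_sd must be > 0", "invalid_parameter")
  peak$height_mAU / noise_sd_mAU
}

#' Assign detected peaks to method analytes
#'
#' Matches each analyte of a method to the detected peak whose apex is
#' nearest the analyte's configured retention time, within a tolerance.
#'
#' @param peaks A `peak_table`.
#' @param method An [instrument_method()] (use the perturbed method when
#'   peaks come from perturbed conditions).
#' @param tol_min Maximum |apex - expected| for a match, minutes.
#' @return The peak table with an `analyte` column, one row per method
#'   analyte; unmatched analytes get NA rows.
#' @export
match_peaks <- function(peaks, method, tol_min = 0.25) {
  qk_check(inherits(method, "instrument_method"),
           "method must be an instrument_method", "invalid_parameter")
  nms <- analyte_names(method)
  rows <- lapply(nms, function(nm) {
    expected <- method$analytes[[nm]]$retention_min
    if (nrow(peaks) > 0) {
      i <- which.min(abs(peaks$apex_min - expected))
      if (abs(peaks$apex_min[i] - expected) <= tol_min) {
        return(cbind(analyte = nm, peaks[i, , drop = FALSE]))
      }
    }
    cbind(analyte = nm, empty_peak_table()[NA_integer_, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
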