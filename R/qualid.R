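# Qualitative identification by the double indicator: relative retention time
# RRT = (tA - t0)/(tR - t0) plus UV spectral similarity of the zero- or
# first-derivative spectra (uncentered cosine, admitting negative values).

#' Relative retention time
#'
#' `RRT = (t_A - t_0) / (t_R - t_0)`: the analyte's retention, dead-time
#' corrected and normalised to the internal reference peak. Invariant under
#' affine transformations of the time axis applied to all three inputs.
#'
#' @param t_A Analyte retention time, minutes.
#' @param t_0 Dead-time (unretained marker) retention, minutes.
#' @param t_R Reference-peak retention time, minutes; must exceed `t_0`.
#' @param analyte Optional analyte name.
#' @return An object of class `rrt_result` with fields `analyte`, `t_A`,
#'   `t_0`, `t_R`, `rrt`.
#' @examples
#' relative_retention_time(6.3, 1.5, 9.7)$rrt
#' @export
relative_retention_time <- function(t_A, t_0, t_R, analyte = NA_character_) {
  qk_check(is.numeric(t_A) && is.numeric(t_0) && is.numeric(t_R),
           "times must be numeric", "invalid_input")
  qk_check(t_R > t_0, "reference must elute after the dead-time marker",
           "invalid_input")
  qk_check(t_A > t_0, "analyte must elute after the dead-time marker",
           "invalid_input")
  structure(list(analyte = analyte, t_A = t_A, t_0 = t_0, t_R = t_R,
                 rrt = (t_A - t_0) / (t_R - t_0)),
            class = "rrt_result")
}

#' @export
print.rrt_result <- function(x, ...) {
  cat(sprintf("<rrt_result> %s: RRT %.4f (tA %.3g, t0 %.3g, tR %.3g)\n",
              if (is.na(x$analyte)) "(unnamed)" else x$analyte,
              x$rrt, x$t_A, x$t_0, x$t_R))
  invisible(x)
}

#' First-derivative UV spectrum
#'
#' Smoothed central-difference derivative dA/dlambda on a uniform grid: each
#' interior point gets the least-squares slope over a centred window (default
#' 5 points); the first and last (window-1)/2 points use one-sided
#' differences.
#'
#' @param s A [uv_spectrum()] (or any list with `wavelengths_nm` and
#'   `absorbance`), at least 5 points on a uniform grid.
#' @param window Odd window size >= 3 for the smoothed slope; default 5.
#' @return A spectrum-shaped object of class `uv_spectrum_deriv` on the same
#'   grid (values may be negative).
#' @export
first_derivative_spectrum <- function(s, window = 5) {
  wl <- s$wavelengths_nm
  ab <- s$absorbance
  n <- length(wl)
  qk_check(n >= 5, "need at least 5 grid points", "invalid_input")
  h <- diff(wl)
  qk_check(max(h) - min(h) < 1e-8 * mean(h) + 1e-12,
           "wavelength grid must be uniform", "invalid_input")
  h <- mean(h)
  qk_check(window >= 3 && window %% 2 == 1 && window <= n,
           "window must be odd, >= 3 and no longer than the grid",
           "invalid_parameter")
  m <- (window - 1) %/% 2
  j <- -m:m
  coefs <- j / (sum(j^2) * h)  # least-squares slope over the window
  d <- numeric(n)
  for (i in (m + 1):(n - m)) d[i] <- sum(coefs * ab[(i - m):(i + m)])
  for (i in seq_len(m)) d[i] <- (ab[i + 1] - ab[i]) / h
  for (i in (n - m + 1):n) d[i] <- (ab[i] - ab[i - 1]) / h
  structure(list(wavelengths_nm = wl, absorbance = d),
            class = "uv_spectrum_deriv")
}

#' UV spectral similarity
#'
#' Uncentered cosine similarity `<s1, s2> / (||s1|| ||s2||)` of two spectra on
#' a common wavelength grid. Symmetric, bounded in [-1, 1], invariant to
#' positive scaling of either spectrum; negative values arise for
#' first-derivative spectra of dissimilar chromophores.
#'
#' @param s1,s2 Spectra (original or derivative) on identical grids.
#' @return Similarity in [-1, 1].
#' @export
spectral_similarity <- function(s1, s2) {
  qk_check(length(s1$wavelengths_nm) == length(s2$wavelengths_nm) &&
             all(abs(s1$wavelengths_nm - s2$wavelengths_nm) < 1e-9),
           "spectra must share the same wavelength grid", "invalid_input")
  v1 <- s1$absorbance; v2 <- s2$absorbance
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  qk_check(n1 > 0 && n2 > 0, "similarity undefined for a zero spectrum",
           "undefined_similarity")
  max(min(sum(v1 * v2) / (n1 * n2), 1), -1)
}

#' Pairwise spectral similarity matrix
#'
#' @param spectra Named list of spectra on a common grid (>= 2).
#' @param order 0 for original spectra, 1 for first-derivative spectra.
#' @param window Derivative window (see [first_derivative_spectrum()]).
#' @return Symmetric matrix with unit diagonal and an `order` attribute.
#' @export
similarity_matrix <- function(spectra, order = 0, window = 5) {
  qk_check(is.list(spectra) && length(spectra) >= 2,
           "need at least 2 spectra", "invalid_input")
  qk_check(order %in% c(0, 1), "order must be 0 or 1", "invalid_parameter")
  if (order == 1) {
    spectra <- lapply(spectra, first_derivative_spectrum, window = window)
  }
  k <- length(spectra)
  labs <- names(spectra)
  if (is.null(labs)) labs <- paste0("spectrum", seq_len(k))
  M <- diag(1, k)
  dimnames(M) <- list(labs, labs)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      M[i, j] <- M[j, i] <- spectral_similarity(spectra[[i]], spectra[[j]])
    }
  }
  attr(M, "order") <- order
  M
}

#' Identify a peak by the RRT + spectral-similarity double indicator
#'
#' A peak is identified as a library analyte only if both indicators agree:
#' its relative retention time matches the library value within a relative
#' tolerance, and its UV spectrum's similarity to the library spectrum meets
#' the threshold.
#'
#' @param peak_rrt Observed relative retention time of the peak.
#' @param peak_spectrum Observed UV spectrum.
#' @param library_entry List with `analyte`, `rrt_ref` and `spectrum` (see
#'   [ld5_rrt_library()]).
#' @param rrt_tol Relative RRT tolerance; default 0.05 (the 5 % robustness
#'   bound of the assay).
#' @param sim_threshold Minimum similarity; default 0.99 for original
#'   spectra.
#' @param order Spectral order (0 or 1) used for the similarity.
#' @return An object of class `identity_decision` with fields `analyte`,
#'   `rrt`, `rrt_ref`, `rrt_match`, `similarity`, `similarity_match`,
#'   `identified` (= both matches).
#' @export
identify_analyte <- function(peak_rrt, peak_spectrum, library_entry,
                             rrt_tol = 0.05, sim_threshold = 0.99,
                             order = 0) {
  qk_check(is.list(library_entry) &&
             all(c("analyte", "rrt_ref", "spectrum") %in% names(library_entry)),
           "library entry must carry analyte, rrt_ref and spectrum",
           "unknown_analyte")
  s1 <- peak_spectrum; s2 <- library_entry$spectrum
  if (order == 1) {
    s1 <- first_derivative_spectrum(s1)
    s2 <- first_derivative_spectrum(s2)
  }
  sim <- spectral_similarity(s1, s2)
  rrt_match <- abs(peak_rrt - library_entry$rrt_ref) /
    library_entry$rrt_ref <= rrt_tol
  sim_match <- sim >= sim_threshold
  structure(list(analyte = library_entry$analyte, rrt = peak_rrt,
                 rrt_ref = library_entry$rrt_ref, rrt_match = rrt_match,
                 similarity = sim, similarity_match = sim_match,
                 identified = rrt_match && sim_match),
            class = "identity_decision")
}

#' @export
print.identity_decision <- function(x, ...) {
  cat(sprintf("<identity_decision> %s: RRT %.4f vs %.4f (%s), similarity %.4f (%s) -> %s\n",
              x$analyte, x$rrt, x$rrt_ref,
              if (x$rrt_match) "match" else "no match",
              x$similarity,
              if (x$similarity_match) "match" else "no match",
              if (x$identified) "IDENTIFIED" else "not identified"))
  invisible(x)
}
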