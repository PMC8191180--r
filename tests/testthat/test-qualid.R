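test_that("relative retention time follows (tA - t0)/(tR - t0)", {
  expect_equal(relative_retention_time(9.7, 1.5, 9.7)$rrt, 1)
  expect_equal(relative_retention_time(6.3, 2.0, 9.7)$rrt, 0.5584,
               tolerance = 1e-4)
  expect_error(relative_retention_time(5, 6, 9.7),
               class = "qamskit_invalid_input")
  expect_error(relative_retention_time(5, 2, 1.5),
               class = "qamskit_invalid_input")
})

test_that("RRT is invariant under affine transformations of the time axis", {
  set.seed(11)
  for (i in 1:50) {
    t0 <- runif(1, 0.5, 3); tR <- t0 + runif(1, 1, 10)
    tA <- t0 + runif(1, 0.1, 15)
    a <- runif(1, 0.2, 5); b <- runif(1, -0.4, 10)
    r1 <- relative_retention_time(tA, t0, tR)$rrt
    r2 <- relative_retention_time(a * tA + b, a * t0 + b, a * tR + b)$rrt
    expect_equal(r2, r1, tolerance = 1e-10)
  }
})

test_that("first-derivative spectra differentiate correctly", {
  grid <- seq(240, 320, by = 2)
  const <- list(wavelengths_nm = grid, absorbance = rep(3, length(grid)))
  expect_true(all(abs(first_derivative_spectrum(const)$absorbance) < 1e-12))

  lin <- list(wavelengths_nm = grid, absorbance = 2 * grid)
  d <- first_derivative_spectrum(lin)
  interior <- 3:(length(grid) - 2)
  expect_equal(d$absorbance[interior], rep(2, length(interior)),
               tolerance = 1e-10)

  g <- uv_spectrum(grid, exp(-(grid - 277)^2 / (2 * 15^2)))
  dg <- first_derivative_spectrum(g)
  # derivative changes sign at the absorbance maximum
  cross <- grid[which(diff(sign(dg$absorbance)) < 0)]
  expect_lt(min(abs(cross - 277)), 2 + 1e-9)

  bad <- list(wavelengths_nm = c(1, 2, 4, 8, 16), absorbance = rep(1, 5))
  expect_error(first_derivative_spectrum(bad), class = "qamskit_invalid_input")
})

test_that("spectral similarity is a bounded symmetric cosine", {
  grid <- 240:260
  s <- uv_spectrum(grid, exp(-(grid - 250)^2 / 20))
  expect_equal(spectral_similarity(s, s), 1)
  e1 <- list(wavelengths_nm = 1:8, absorbance = c(1, rep(0, 7)))
  e2 <- list(wavelengths_nm = 1:8, absorbance = c(0, 1, rep(0, 6)))
  expect_equal(spectral_similarity(e1, e2), 0)
  neg <- list(wavelengths_nm = grid, absorbance = -s$absorbance)
  expect_equal(spectral_similarity(s, neg), -1)
  zero <- list(wavelengths_nm = grid, absorbance = rep(0, length(grid)))
  expect_error(spectral_similarity(s, zero),
               class = "qamskit_undefined_similarity")
  # invariant to positive scaling
  sc <- list(wavelengths_nm = grid, absorbance = 17.3 * s$absorbance)
  expect_equal(spectral_similarity(s, sc), 1, tolerance = 1e-12)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  specs <- ld5_spectra()
  for (ord in 0:1) {
    M <- similarity_matrix(specs, order = ord)
    expect_equal(dim(M), c(5, 5))
    expect_equal(unname(diag(M)), rep(1, 5))
    expect_equal(M, t(M))
    expect_true(all(M >= -1 & M <= 1))
  }
  two <- similarity_matrix(list(a = specs[[1]], b = specs[[1]]))
  expect_true(all(abs(two - 1) < 1e-12))
})

test_that("first-derivative spectra discriminate more than the originals", {
  M0 <- similarity_matrix(ld5_spectra(), order = 0)
  M1 <- similarity_matrix(ld5_spectra(), order = 1)
  expect_lt(mean(M1[upper.tri(M1)]), mean(M0[upper.tri(M0)]))
})

test_that("the double indicator requires both RRT and spectral agreement", {
  lib <- ld5_rrt_library()
  specs <- ld5_spectra()
  ok <- identify_analyte(lib$torasemide$rrt_ref, specs$torasemide,
                         lib$torasemide)
  expect_true(ok$identified)

  off_rrt <- identify_analyte(1.5 * lib$torasemide$rrt_ref, specs$torasemide,
                              lib$torasemide)
  expect_false(off_rrt$rrt_match)
  expect_false(off_rrt$identified)

  wrong_spec <- identify_analyte(lib$torasemide$rrt_ref, specs$bumetanide,
                                 lib$torasemide)
  expect_true(wrong_spec$rrt_match)
  expect_false(wrong_spec$similarity_match)
  expect_false(wrong_spec$identified)

  expect_error(identify_analyte(1, specs$torasemide, list(analyte = "x")),
               class = "qamskit_unknown_analyte")
})

test_that("identified is always the conjunction of the two indicators", {
  lib <- ld5_rrt_library()
  specs <- ld5_spectra()
  set.seed(7)
  for (i in 1:20) {
    nm <- sample(names(lib), 1)
    rrt <- lib[[nm]]$rrt_ref * runif(1, 0.8, 1.2)
    sp <- specs[[sample(names(specs), 1)]]
    dec <- identify_analyte(rrt, sp, lib[[nm]])
    expect_identical(dec$identified, dec$rrt_match && dec$similarity_match)
  }
})
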