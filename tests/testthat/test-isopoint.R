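make_sens <- function(slope, se = 0.01, wl = NULL) {
  n <- length(slope)
  if (is.null(wl)) wl <- seq(500, by = 10, length.out = n)
  structure(list(wavelengths = wl, slope = slope,
                 se = rep_len(se, n), n_obs = 10),
            class = "sensitivity_spectrum")
}

test_that("depth sensitivity is the per-band OLS slope", {
  wl <- c(500, 510, 520)
  depths <- c(1, 2, 3, 5, 8)

  flat <- matrix(4, length(depths), 3)
  s0 <- depth_sensitivity(flat, depths, wl)
  expect_equal(s0$slope, c(0, 0, 0))
  expect_equal(s0$se, c(0, 0, 0))

  # exact line: a + b * depth per band
  b <- c(-0.3, 0, 2)
  a <- c(1, 5, -2)
  lin <- outer(depths, b) + matrix(a, length(depths), 3, byrow = TRUE)
  s1 <- depth_sensitivity(lin, depths, wl)
  expect_equal(s1$slope, b, tolerance = 1e-12)
  expect_equal(s1$se, c(0, 0, 0), tolerance = 1e-10)

  expect_error(depth_sensitivity(flat[1:2, ], depths[1:2], wl),
               "3 distinct depths")
  expect_error(depth_sensitivity(flat, rep(2, 5), wl), "3 distinct depths")
})

test_that("simulated high-concentration scene has the expected slope signs", {
  sens <- scene_sensitivity(concentration = 0.10, noise_sigma = 0)
  iso <- test_scene(0.10, 0)$truth$iso_wavelength_analytic
  below <- sens$wavelengths < iso - 10
  above <- sens$wavelengths > iso + 10
  expect_true(all(sens$slope[below] > 0))
  expect_true(all(sens$slope[above] < 0))
})

test_that("iso-point interpolation is exact for a symmetric crossing", {
  res <- detect_isopoint(make_sens(c(1, 1, -1, -1)))
  expect_identical(res$status, "found")
  expect_equal(res$iso_wavelength, 515)  # midpoint of 510 and 520
})

test_that("one-sided sensitivity spectra are classified absent", {
  res <- detect_isopoint(make_sens(c(-1, -1.4, -0.9, -1.1, -0.8)))
  expect_identical(res$status, "absent")
  expect_true(is.na(res$iso_wavelength))
})

test_that("grazing sensitivity spectra are classified boundary", {
  # dips to ~zero without a sign change (relative dip criterion)
  res <- detect_isopoint(make_sens(c(1, 0.5, 0.01, 0.5, 1), se = 1e-6))
  expect_identical(res$status, "boundary")
  expect_equal(res$iso_wavelength, 520)
})

test_that("well-separated multiple crossings raise an ambiguity error", {
  s <- make_sens(c(1, 1, -1, -1, -1, -1, 1, 1))
  expect_error(detect_isopoint(s), class = "hsdepth_ambiguous_isopoint")
  cnd <- tryCatch(detect_isopoint(s), condition = function(c) c)
  expect_length(cnd$candidates, 2)
})

test_that("detection is invariant to a global positive rescaling", {
  sens <- scene_sensitivity(concentration = 0.10, noise_sigma = 0.01,
                            seed = 11)
  r1 <- detect_isopoint(sens)
  scaled <- sens
  scaled$slope <- sens$slope * 37.5
  scaled$se <- sens$se * 37.5
  r2 <- detect_isopoint(scaled)
  expect_identical(r1$status, r2$status)
  expect_equal(r1$iso_wavelength, r2$iso_wavelength, tolerance = 1e-12)
})

test_that("detected iso-point matches the generator's analytic crossover", {
  sens <- scene_sensitivity(concentration = 0.10, noise_sigma = 0)
  res <- detect_isopoint(sens)
  iso_true <- test_scene(0.10, 0)$truth$iso_wavelength_analytic
  expect_identical(res$status, "found")
  expect_lt(abs(res$iso_wavelength - iso_true), 6)
})

test_that("depth parameter is 1 - I_abs/I_iso with a guarded denominator", {
  expect_equal(depth_parameter(0.3, 0.6), 0.5)
  expect_equal(depth_parameter(0.42, 0.42), 0)
  expect_warning(out <- depth_parameter(c(0.3, 0.2), c(0.6, 0)),
                 "masked")
  expect_equal(out[1], 0.5)
  expect_true(is.na(out[2]))
})

test_that("whole-image depth map equals the per-pixel brute-force loop", {
  set.seed(7)
  for (rep in 1:100) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(5:12, 1))
    wl <- 500 + seq_len(d[3]) * 3
    vals <- array(runif(prod(d), 0.02, 1), d)
    if (rep %% 4 == 0) vals[1, 1, ] <- 0   # exercise the masking path
    cube <- spectral_cube(vals, wl)
    li <- sample(wl, 1); la <- sample(wl, 1)
    map <- suppressWarnings(
      depth_parameter_map(cube, li, la, baseline = FALSE))
    expect_equal(map$values, suppressWarnings(naive_depth_map(cube, li, la)),
                 tolerance = 1e-15)
  }
})

test_that("identical band choices give a zero map before baseline handling", {
  cube <- spectral_cube(array(runif(4 * 4 * 6, 0.1, 1), c(4, 4, 6)),
                        seq(550, 575, by = 5))
  map <- depth_parameter_map(cube, 560, 560, baseline = FALSE)
  expect_equal(map$values, matrix(0, 4, 4))
  expect_error(depth_parameter_map(cube, 700), "outside")
})

test_that("baseline-subtracted depth parameter is monotone in cover depth", {
  pp <- preprocessed_scene(concentration = 0.10, noise_sigma = 0)
  truth <- pp$scene$truth
  map <- depth_parameter_map(pp$banded,
                             truth$iso_wavelength_analytic,
                             background_region =
                               truth$lateral_mm >=
                                 stats::quantile(truth$lateral_mm, 0.9))
  j <- which.min(abs(truth$y_mm - truth$axis_entry_mm[2]))
  on_axis <- which(truth$inclusion_mask[, j])
  depths <- truth$depth_map[on_axis, j]
  di <- map$values[on_axis, j]
  ord <- order(depths)
  # strict in the interior; the outermost two scan columns can tie
  # exactly because the median filter's reflected border duplicates
  # order statistics there
  interior <- ord[3:(length(ord) - 2)]
  expect_true(all(diff(di[interior]) < 0))
  expect_true(all(diff(di[ord]) <= 0))
  # decays toward the background level as depth grows
  expect_lt(abs(di[ord][length(di)]), 0.1 * max(abs(di)))
})
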