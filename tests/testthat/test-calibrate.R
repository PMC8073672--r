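scene_map_profile <- function(noise_sigma = 0, seed = 1) {
  pp <- preprocessed_scene(concentration = 0.10,
                           noise_sigma = noise_sigma, seed = seed)
  truth <- pp$scene$truth
  map <- depth_parameter_map(pp$banded, truth$iso_wavelength_analytic,
                             background_region =
                               truth$lateral_mm >=
                                 stats::quantile(truth$lateral_mm, 0.9))
  list(map = map, truth = truth,
       profile = extract_profile(map, truth, "along"))
}

test_that("along-axis profiles are monotone and depth-labelled", {
  sp <- scene_map_profile(0)
  prof <- sp$profile
  expect_s3_class(prof, "depth_profile")
  expect_true(all(diff(prof$position_mm) > 0))
  ok <- which(is.finite(prof$true_depth_mm))
  expect_gt(length(ok), 30)
  # strictly decreasing in the interior; exact ties can occur in the
  # outermost scan columns from the median filter's reflected border
  inner <- ok[3:(length(ok) - 2)]
  expect_true(all(diff(prof$depth_param[inner]) < 0))
  expect_true(all(diff(prof$depth_param[ok]) <= 0))
  # cover depth itself ramps with the position along the axis
  expect_true(all(diff(prof$true_depth_mm[ok]) > 0))
})

test_that("across-axis profiles show blur wider than the 2 mm channel", {
  sp <- scene_map_profile(0)
  # cross the channel where it is a few mm deep
  prof <- extract_profile(sp$map, sp$truth, "across", offset_mm = 10)
  peak <- max(prof$depth_param, na.rm = TRUE)
  above <- prof$position_mm[!is.na(prof$depth_param) &
                              prof$depth_param >= peak / 2]
  expect_gt(diff(range(above)), 2)
})

test_that("profiles that miss the inclusion raise an empty-profile signal", {
  sp <- scene_map_profile(0)
  expect_error(extract_profile(sp$map, sp$truth, "along", offset_mm = 8),
               class = "hsdepth_empty_profile")
})

test_that("inner_fraction trims the stated sample counts", {
  prof10 <- hsdepth:::new_profile(1:10, rnorm(10))
  expect_equal(inner_fraction(prof10, 0.6)$true_depth_mm, 3:8)
  prof11 <- hsdepth:::new_profile(1:11, rnorm(11))
  expect_equal(inner_fraction(prof11, 0.6)$true_depth_mm, 3:9)
  expect_equal(inner_fraction(prof10, 1), prof10)
  expect_error(inner_fraction(prof10, 0), "fraction")
  expect_error(inner_fraction(prof10, 1.2), "fraction")
})

test_that("linear fits recover exact and noisy lines", {
  d <- seq(0, 5, length.out = 20)
  exact <- hsdepth:::new_profile(d, 2 * d + 1)
  fl <- fit_linear(exact)
  expect_equal(fl$slope, 2, tolerance = 1e-12)
  expect_equal(fl$intercept, 1, tolerance = 1e-12)
  expect_equal(fl$r2, 1)

  flat <- fit_linear(hsdepth:::new_profile(d, rep(0.4, 20)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  set.seed(99)
  dn <- runif(200, 0, 8)
  noisy <- fit_linear(hsdepth:::new_profile(dn, 2 * dn + 1 +
                                              rnorm(200, 0, 0.5)))
  expect_lt(abs(noisy$slope - 2), 3 * noisy$se_slope)

  expect_error(fit_linear(hsdepth:::new_profile(c(1, 1, 1), c(1, 2, 3))),
               "non-constant")
})

test_that("exponential fits recover exact curves and flag degeneracy", {
  d <- seq(0, 10, length.out = 20)
  fe <- fit_exponential(hsdepth:::new_profile(d, 0.4 * exp(-0.5 * d) + 0.01))
  expect_false(fe$degenerate)
  expect_equal(fe$amplitude, 0.4, tolerance = 1e-6)
  expect_equal(fe$rate, 0.5, tolerance = 1e-6)
  expect_equal(fe$offset, 0.01, tolerance = 1e-6)
  expect_equal(fe$r2, 1, tolerance = 1e-9)

  const <- fit_exponential(hsdepth:::new_profile(d, rep(0.3, 20)))
  expect_true(const$degenerate)
  expect_equal(const$amplitude + const$offset, 0.3)

  expect_error(fit_exponential(hsdepth:::new_profile(1:3, c(1, 2, 3))),
               ">= 4")
})

test_that("noise-free deep-regime profiles are near-exponential", {
  sp <- scene_map_profile(0)
  prof <- sp$profile
  deep <- prof[is.finite(prof$true_depth_mm) & prof$true_depth_mm > 4, ]
  fe <- fit_exponential(deep)
  expect_gte(fe$r2, 0.99)
  expect_gte(fe$rate, 0)
})

test_that("regime segmentation recovers constructed breakpoints", {
  # exactly linear everywhere: maximal breakpoint, empty exponential
  d <- seq(0, 8, by = 0.25)
  cal_lin <- segment_regimes(hsdepth:::new_profile(d, 0.3 - 0.02 * d))
  expect_equal(cal_lin$breakpoint_depth_mm, 8)
  expect_null(cal_lin$exponential)
  expect_equal(cal_lin$r2_total, 1)

  # piecewise data glued continuously at 4 mm
  d <- seq(0, 10, by = 0.25)
  y <- ifelse(d <= 4, 0.5 - 0.1 * d,
              0.3 * exp(-0.6 * d) + (0.1 - 0.3 * exp(-2.4)))
  cal <- segment_regimes(hsdepth:::new_profile(d, y))
  expect_lt(abs(cal$breakpoint_depth_mm - 4), 0.25 + 1e-9)
  expect_gt(cal$r2_total, 0.999)
})

test_that("piecewise SSE never exceeds either single-model fit", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sort(runif(40, 0, 10))
    y <- 0.3 * exp(-0.4 * d) + 0.02 + rnorm(40, 0, 0.01)
    prof <- hsdepth:::new_profile(d, y)
    cal <- segment_regimes(prof)
    sse_lin <- fit_linear(prof)$sse
    sse_exp <- fit_exponential(prof)$sse
    expect_lte(cal$sse_total, sse_lin + 1e-12)
    expect_lte(cal$sse_total, sse_exp + 1e-9 * max(1, sse_exp))
    expect_lte(cal$r2_total, 1)
  }
})

test_that("simulator calibration explains the variance, more so inner-60%", {
  sp <- scene_map_profile(0)
  cal_full <- segment_regimes(sp$profile)
  cal_in <- segment_regimes(inner_fraction(sp$profile, 0.6),
                            mask_fraction = 0.6)
  expect_gte(cal_in$r2_total, 0.95)
  expect_gte(cal_in$r2_total, cal_full$r2_total - 1e-9)
  expect_equal(cal_in$mask_fraction, 0.6)
  expect_gte(cal_in$exponential$rate, 0)
  expect_true(cal_in$breakpoint_depth_mm >=
                min(sp$profile$true_depth_mm, na.rm = TRUE) &&
              cal_in$breakpoint_depth_mm <=
                max(sp$profile$true_depth_mm, na.rm = TRUE))
})

test_that("calibration inversion round-trips exactly on both branches", {
  cal <- hsdepth:::new_calibration(
    bp = 5,
    lin = list(slope = -0.05, intercept = 0.4, r2 = 1, sse = 0, n = 10),
    ex = list(amplitude = 0.3, rate = 0.4, offset = 0.01, r2 = 1,
              sse = 0, n = 10, degenerate = FALSE),
    y_all = c(0, 1), sse = 0, rng_lin = c(0, 5), rng_exp = c(5, 10),
    mask_fraction = 1)
  expect_equal(invert_depth(-0.05 * 3 + 0.4, cal), 3)
  expect_equal(invert_depth(0.3 * exp(-0.4 * 7) + 0.01, cal), 7)
  expect_warning(out <- invert_depth(9.9, cal), "outside")
  expect_true(is.na(out))
})

test_that("round-trip depth errors are small shallow and grow with depth", {
  sp <- scene_map_profile(0)
  prof <- inner_fraction(sp$profile, 0.6)
  cal <- segment_regimes(prof, mask_fraction = 0.6)
  lin <- prof[is.finite(prof$true_depth_mm) &
                prof$true_depth_mm <= cal$breakpoint_depth_mm, ]
  pred <- suppressWarnings(invert_depth(lin$depth_param, cal))
  rmse <- sqrt(mean((pred - lin$true_depth_mm)^2, na.rm = TRUE))
  expect_lte(rmse, 0.1)

  # residuals grow across depth bins on noisy data (trend, not pointwise)
  spn <- scene_map_profile(noise_sigma = 0.01, seed = 5)
  profn <- spn$profile[is.finite(spn$profile$true_depth_mm), ]
  caln <- segment_regimes(profn)
  predn <- suppressWarnings(invert_depth(profn$depth_param, caln))
  err <- abs(predn - profn$true_depth_mm)
  bins <- cut(profn$true_depth_mm, breaks = c(0, 2.5, 5, 7.5, 10.5),
              include.lowest = TRUE)
  rmse_bin <- tapply(err, bins, function(e) sqrt(mean(e^2, na.rm = TRUE)))
  centers <- tapply(profn$true_depth_mm, bins, mean)
  trend <- stats::coef(stats::lm(rmse_bin ~ centers))[2]
  expect_gt(trend, 0)
})
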