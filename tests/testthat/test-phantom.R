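test_that("water-filled inclusion has positive contrast and no iso-point", {
  sc <- test_scene(concentration = 0, noise_sigma = 0)
  wl <- sc$raw$wavelengths
  cc <- contrast_spectrum(sc$inclusion, wl)
  expect_true(all(cc > 0))
  expect_true(is.na(sc$truth$iso_wavelength_analytic))

  # inclusion brighter than background at every band
  axis_px <- which(sc$truth$inclusion_mask[, 48])[1]
  bg_px <- which.max(sc$truth$lateral_mm[, 1])
  expect_true(all(sc$raw$values[axis_px, 48, ] >
                    sc$raw$values[bg_px, 1, ]))
})

test_that("high-concentration contrast changes sign exactly once near 575 nm", {
  sc <- test_scene(concentration = 0.10, noise_sigma = 0)
  wl <- sc$raw$wavelengths
  cc <- contrast_spectrum(sc$inclusion, wl)
  signs <- sign(cc[cc != 0])
  expect_equal(sum(diff(signs) != 0), 1)
  iso <- sc$truth$iso_wavelength_analytic
  expect_true(iso > min(wl) && iso < max(wl))
  expect_equal(iso, 575, tolerance = 0.01)
  expect_lt(max(cc[wl < iso - 2]), 0)
  expect_gt(min(cc[wl > iso + 2]), 0)
})

test_that("noise-free reflectance at the analytic iso-point is depth invariant", {
  # band grid hitting the crossover exactly, no spectral PSF mixing
  inc <- inclusion_geometry()
  inc$scatter_contrast <- extinction(inc$absorber, 575)  # C(575) = 0
  acq <- desk_acquisition(noise_sigma = 0)
  acq$band_sampling_nm <- 1
  acq$spectral_psf_fwhm_nm <- 1
  sc <- simulate_cube(medium_optics(), inc, acq)
  expect_equal(sc$truth$iso_wavelength_analytic, 575, tolerance = 1e-6)
  b_iso <- band_index(sc$raw, 575)
  on_axis <- sc$truth$inclusion_mask[, 48]
  vals <- sc$raw$values[on_axis, 48, b_iso]
  expect_lt(stats::sd(vals), 1e-12)

  # off the iso band the same pixels do vary with depth
  expect_gt(stats::sd(sc$raw$values[on_axis, 48, band_index(sc$raw, 550)]),
            1e-6)
})

test_that("perturbation decays with depth and has the documented sign structure", {
  sc <- test_scene(concentration = 0.10, noise_sigma = 0, psf = "delta")
  truth <- sc$truth
  iso <- truth$iso_wavelength_analytic
  wl <- sc$raw$wavelengths
  R0 <- truth$background_spectrum
  j <- 48  # line through the axis
  on_axis <- which(truth$inclusion_mask[, j])
  depths <- truth$depth_map[on_axis, j]
  ord <- order(depths)
  for (b in c(band_index(sc$raw, 430), band_index(sc$raw, 550),
              band_index(sc$raw, 600), band_index(sc$raw, 660))) {
    dev <- sc$raw$values[on_axis, j, b][ord] - R0[b]
    expect_true(all(diff(abs(dev)) < 0))          # |R - R0| shrinks
    if (wl[b] < iso) {
      expect_true(all(dev < 0))                   # darker when closer
      expect_true(all(diff(dev) > 0))             # R rises with depth
    } else {
      expect_true(all(dev > 0))                   # brighter when closer
      expect_true(all(diff(dev) < 0))             # R falls with depth
    }
  }
})

test_that("simulation is deterministic for identical spec and seed", {
  a <- simulate_cube(acq = desk_acquisition(noise_sigma = 0.02, seed = 7))
  b <- simulate_cube(acq = desk_acquisition(noise_sigma = 0.02, seed = 7))
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$reference$values, b$reference$values)
  c <- simulate_cube(acq = desk_acquisition(noise_sigma = 0.02, seed = 8))
  expect_false(identical(a$raw$values, c$raw$values))
})

test_that("scene without inclusion is the background spectrum everywhere", {
  acq <- desk_acquisition(noise_sigma = 0)
  acq$spectral_psf_fwhm_nm <- acq$band_sampling_nm
  sc <- simulate_cube(medium_optics(), inclusion = NULL, acq = acq)
  R0 <- sc$truth$background_spectrum
  for (b in c(1, 60, 132))
    expect_equal(as.vector(sc$raw$values[, , b]),
                 rep(R0[b], 48 * 96), tolerance = 1e-12)
  expect_false(any(sc$truth$inclusion_mask))
  expect_true(all(sc$truth$depth_map == -1))
})

test_that("inclusion outside the scene is rejected", {
  inc <- inclusion_geometry(entry_mm = c(-5, 10, 0),
                            exit_mm = c(20, 10, 8))
  expect_error(simulate_cube(inclusion = inc, acq = desk_acquisition()),
               "outside the .* scene")
})

test_that("fixture suite is deterministic and scene contrasts are as labelled", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture_suite(d1, seed = 3)
  make_fixture_suite(d2, seed = 3)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)

  # boundary scene: contrast touches zero without changing sign
  cfg <- read_config(file.path(d1, "boundary", "scene.cfg"))
  inc <- inclusion_geometry()
  inc$absorber$concentration <- cfg$concentration
  cc <- contrast_spectrum(inc, seq(407, 670, by = 0.5))
  expect_lt(min(abs(cc)), 1e-10)
  expect_gte(min(cc), 0)

  # cube dimensions match the acquisition spec
  cube <- read_envi(file.path(d1, "high", "cube"))
  expect_equal(dim(cube$values)[1:2], c(cfg$n_x, cfg$n_y))
  unlink(c(d1, d2), recursive = TRUE)
})
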