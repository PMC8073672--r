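#' Inclusion geometry and contrast
#'
#' A cylindrical channel of the given diameter drilled through the
#' substrate between two surface-projected points; its cover depth
#' varies affinely with position along the axis, emulating a channel
#' drilled diagonally from the top to the bottom surface.  The channel
#' perturbs the background reflectance with a wavelength-dependent
#' contrast
#' \deqn{C(\lambda) = c_s - c_a\,\epsilon(\lambda),}
#' the balance of a scattering-driven brightening (`scatter_contrast`,
#' \eqn{c_s}) and an absorption-driven darkening proportional to the
#' fill absorber's extinction (`absorption_contrast_gain`, \eqn{c_a}).
#' Where \eqn{C} changes sign the inclusion has an iso-point: a
#' wavelength whose surface reflectance is independent of cover depth.
#'
#' @param diameter_mm channel diameter, mm (> 0).
#' @param entry_mm,exit_mm numeric length-3 vectors `(x_mm, y_mm,
#'   cover_depth_mm)` giving the channel-top position and cover depth at
#'   the two ends of the axis.
#' @param absorber an [absorber_spec] describing the channel fill; use
#'   `concentration = 0` for water.
#' @param scatter_contrast dimensionless brightening amplitude
#'   \eqn{c_s \ge 0}.
#' @param absorption_contrast_gain dimensionless darkening gain
#'   \eqn{c_a \ge 0} multiplying the fill extinction (mm^-1).
#' @param blur_sigma0_mm,blur_sigma_slope lateral blur of the channel's
#'   apparent footprint: Gaussian sigma `sigma0 + slope * depth` (mm,
#'   mm/mm).  Scattering widens the apparent inclusion with depth.
#' @return object of class `inclusion_geometry`.
#' @export
inclusion_geometry <- function(diameter_mm = 2,
                               entry_mm = c(0, 10.75, 0),
                               exit_mm = c(24.7, 10.75, 10),
                               absorber = absorber_spec(),
                               scatter_contrast = 0.082,
                               absorption_contrast_gain = 1,
                               blur_sigma0_mm = 0.3,
                               blur_sigma_slope = 0.5) {
  if (diameter_mm <= 0) stop("`diameter_mm` must be > 0", call. = FALSE)
  if (scatter_contrast < 0 || absorption_contrast_gain < 0)
    stop("contrast amplitudes must be >= 0", call. = FALSE)
  if (length(entry_mm) != 3 || length(exit_mm) != 3)
    stop("`entry_mm`/`exit_mm` must be (x, y, depth) triples", call. = FALSE)
  if (entry_mm[3] < 0 || exit_mm[3] < 0)
    stop("cover depths must be >= 0", call. = FALSE)
  structure(list(diameter_mm = diameter_mm, entry_mm = entry_mm,
                 exit_mm = exit_mm, absorber = absorber,
                 scatter_contrast = scatter_contrast,
                 absorption_contrast_gain = absorption_contrast_gain,
                 blur_sigma0_mm = blur_sigma0_mm,
                 blur_sigma_slope = blur_sigma_slope),
            class = "inclusion_geometry")
}

#' Spectral contrast of an inclusion
#'
#' @param inclusion an [inclusion_geometry].
#' @param lambda_nm wavelength(s), nm.
#' @return \eqn{C(\lambda) = c_s - c_a \epsilon(\lambda)}, vectorized.
#' @export
contrast_spectrum <- function(inclusion, lambda_nm) {
  stopifnot(inherits(inclusion, "inclusion_geometry"))
  inclusion$scatter_contrast -
    inclusion$absorption_contrast_gain *
      extinction(inclusion$absorber, lambda_nm)
}

#' Absorber concentration at which the iso-point sits at the boundary
#'
#' The concentration for which the contrast minimum just touches zero,
#' so the depth-sensitivity spectrum grazes zero without a sign change
#' (iso-point "at the boundary").  Requires the absorber's extinction
#' peak to lie inside the simulated band range.
#'
#' @param inclusion an [inclusion_geometry].
#' @return dimensionless concentration.
#' @export
boundary_concentration <- function(inclusion) {
  stopifnot(inherits(inclusion, "inclusion_geometry"))
  a <- inclusion$absorber
  if (inclusion$absorption_contrast_gain * a$peak_extinction <= 0)
    stop("inclusion has no absorption contrast", call. = FALSE)
  inclusion$scatter_contrast /
    (inclusion$absorption_contrast_gain * a$peak_extinction)
}

#' Analytic iso-point wavelength of an inclusion
#'
#' Root of the contrast \eqn{C(\lambda)} on the given band range, found
#' by bisection between the bracketing grid wavelengths; `NA` when
#' \eqn{C} has no sign change on the range (no iso-point, e.g. a
#' water-filled channel).
#'
#' @param inclusion an [inclusion_geometry].
#' @param band_range_nm numeric `(low, high)` wavelength range, nm.
#' @return iso-point wavelength in nm, or `NA_real_`.
#' @export
analytic_iso_wavelength <- function(inclusion, band_range_nm = c(407, 670)) {
  grid <- seq(band_range_nm[1], band_range_nm[2], length.out = 2048)
  cc <- contrast_spectrum(inclusion, grid)
  flips <- which(cc[-1] * cc[-length(cc)] < 0)
  if (length(flips) == 0) {
    exact <- which(cc == 0)
    return(if (length(exact)) grid[exact[1]] else NA_real_)
  }
  i <- flips[length(flips)]  # red-side crossing
  stats::uniroot(function(l) contrast_spectrum(inclusion, l),
                 lower = grid[i], upper = grid[i + 1],
                 tol = 1e-10)$root
}

#' Acquisition specification of the line-scanning camera
#'
#' Defaults reproduce the native scanner geometry: a 95 x 500 pixel
#' scene at 260 um (scan, `x`) by 43 um (line, `y`) pitch and 950
#' spectral bands spanning 407-670 nm (about 0.28 nm per band), with an
#' effective spectral resolution of 10 nm modelled as a Gaussian PSF
#' along the band axis.
#'
#' @param n_x,n_y pixel counts along scan and line directions.
#' @param pitch_x_um,pitch_y_um pixel pitch, micrometres.
#' @param band_range_nm numeric `(low, high)` spectral range, nm.
#' @param band_sampling_nm band spacing, nm per band (> 0).
#' @param spectral_psf_fwhm_nm effective spectral resolution, nm; must
#'   be at least the band sampling.  Equal to the sampling means no
#'   spectral blurring.
#' @param illumination per-band relative source power: a single number,
#'   a vector over bands, or a function of wavelength; default flat.
#' @param noise_sigma relative standard deviation of the multiplicative
#'   Gaussian detector noise (>= 0).
#' @param seed integer RNG seed for the noise, or `NULL`.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_x = 95, n_y = 500, pitch_x_um = 260,
                             pitch_y_um = 43,
                             band_range_nm = c(407, 670),
                             band_sampling_nm = (670 - 407) / 949,
                             spectral_psf_fwhm_nm = 10,
                             illumination = 1, noise_sigma = 0.01,
                             seed = NULL) {
  if (band_range_nm[1] >= band_range_nm[2])
    stop("`band_range_nm` must be (low, high) with low < high", call. = FALSE)
  if (band_sampling_nm <= 0)
    stop("`band_sampling_nm` must be > 0", call. = FALSE)
  if (spectral_psf_fwhm_nm < band_sampling_nm)
    stop("`spectral_psf_fwhm_nm` must be >= the band sampling", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
                 band_range_nm = band_range_nm,
                 band_sampling_nm = band_sampling_nm,
                 spectral_psf_fwhm_nm = spectral_psf_fwhm_nm,
                 illumination = illumination, noise_sigma = noise_sigma,
                 seed = seed),
            class = "acquisition_spec")
}

#' Reduced-size acquisition for fast desk-scale scenes
#'
#' Same physical scene extent (24.7 mm x 21.5 mm) and spectral range as
#' the native geometry, sampled at 48 x 96 pixels and 2 nm bands so a
#' full scene simulates in well under a second.
#'
#' @inheritParams acquisition_spec
#' @param ... passed on to [acquisition_spec()].
#' @return an `acquisition_spec`.
#' @export
desk_acquisition <- function(noise_sigma = 0.01, seed = NULL, ...) {
  acquisition_spec(n_x = 48, n_y = 96,
                   pitch_x_um = 95 * 260 / 48, pitch_y_um = 500 * 43 / 96,
                   band_sampling_nm = 2, noise_sigma = noise_sigma,
                   seed = seed, ...)
}

acq_wavelengths <- function(acq) {
  n <- floor((acq$band_range_nm[2] - acq$band_range_nm[1]) /
               acq$band_sampling_nm + 1e-9) + 1
  acq$band_range_nm[1] + (seq_len(n) - 1) * acq$band_sampling_nm
}

acq_illumination <- function(acq, wavelengths) {
  il <- acq$illumination
  if (is.function(il)) il <- il(wavelengths)
  if (length(il) == 1) il <- rep(il, length(wavelengths))
  if (length(il) != length(wavelengths))
    stop("illumination vector length does not match band count",
         call. = FALSE)
  if (any(il <= 0)) stop("illumination must be positive", call. = FALSE)
  il
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Lateral footprint of the channel: a top-hat of half-width r blurred
# with a depth-dependent Gaussian, evaluated in closed form.
lateral_amplitude <- function(u_mm, radius_mm, sigma_mm) {
  out <- numeric(length(u_mm))
  z <- sigma_mm <= 0
  if (any(z)) out[z] <- as.numeric(abs(u_mm[z]) <= radius_mm)
  if (any(!z)) {
    s <- sqrt(2) * sigma_mm[!z]
    out[!z] <- 0.5 * (erf((radius_mm - u_mm[!z]) / s) +
                        erf((radius_mm + u_mm[!z]) / s))
  }
  out
}

# Per-pixel geometry relative to the channel axis: along-axis position
# (clamped to the segment), lateral distance to the segment, and the
# affine cover depth (clamped at the surface).
channel_geometry <- function(entry_mm, exit_mm, x_mm, y_mm) {
  p0 <- entry_mm[1:2]
  p1 <- exit_mm[1:2]
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) stop("inclusion entry and exit coincide", call. = FALSE)
  xg <- matrix(x_mm, length(x_mm), length(y_mm))
  yg <- matrix(y_mm, length(x_mm), length(y_mm), byrow = TRUE)
  t_raw <- ((xg - p0[1]) * v[1] + (yg - p0[2]) * v[2]) / len
  t_cl <- pmin(pmax(t_raw, 0), len)
  px <- p0[1] + t_cl / len * v[1]
  py <- p0[2] + t_cl / len * v[2]
  u <- sqrt((xg - px)^2 + (yg - py)^2)
  depth <- entry_mm[3] + (exit_mm[3] - entry_mm[3]) * t_cl / len
  depth <- pmax(depth, 0)
  list(along_mm = t_cl, lateral_mm = u, depth_mm = depth, axis_length = len)
}

#' Simulate a hyperspectral phantom scene
#'
#' Forward model: the substrate reflects with the diffusion-
#' approximation background \eqn{R_0(\lambda)}
#' ([background_reflectance]); the buried channel perturbs it as
#' \deqn{R(\lambda) = R_0(\lambda)\,[1 + C(\lambda)\,
#'   W(\lambda, d)\, S(u, d)]}
#' with contrast \eqn{C} ([contrast_spectrum]), depth kernel
#' \eqn{W = e^{-2\mu_{eff} d}} ([sensitivity_kernel]) and the lateral
#' blur profile \eqn{S} (a top-hat of the channel's half-width
#' convolved with a Gaussian whose sigma grows with depth).  Raw
#' intensities are reflectance times the illumination spectrum,
#' convolved with the spectral PSF, with multiplicative Gaussian
#' detector noise; the white-reference frame applies the same
#' acquisition model to a flat reflectance standard.
#'
#' @param substrate a [medium_optics].
#' @param inclusion an [inclusion_geometry], or `NULL` for an
#'   unperturbed scene.
#' @param acq an [acquisition_spec].
#' @param reference_reflectance reflectance of the white standard
#'   (barium-sulfate-like), default 0.99.
#' @return list with elements `raw` ([spectral_cube]), `reference`
#'   ([spectral_cube], the white-standard frame) and `truth` (class
#'   `ground_truth`: `depth_map` in mm with sentinel -1 outside the
#'   channel, `inclusion_mask`, `iso_wavelength_analytic` (nm or `NA`),
#'   `background_spectrum`, plus the per-pixel axis geometry).
#' @export
#' @examples
#' sc <- simulate_cube(medium_optics(), inclusion_geometry(),
#'                     desk_acquisition(noise_sigma = 0, seed = 1))
#' sc$truth$iso_wavelength_analytic
simulate_cube <- function(substrate = medium_optics(),
                          inclusion = inclusion_geometry(),
                          acq = acquisition_spec(),
                          reference_reflectance = 0.99) {
  stopifnot(inherits(substrate, "medium_optics"),
            inherits(acq, "acquisition_spec"))
  wl <- acq_wavelengths(acq)
  il <- acq_illumination(acq, wl)
  nb <- length(wl)
  nx <- acq$n_x; ny <- acq$n_y; npix <- nx * ny
  x_mm <- (seq_len(nx) - 0.5) * acq$pitch_x_um / 1000
  y_mm <- (seq_len(ny) - 0.5) * acq$pitch_y_um / 1000
  R0 <- background_reflectance(substrate, wl)

  if (!is.null(inclusion)) {
    stopifnot(inherits(inclusion, "inclusion_geometry"))
    ext_x <- nx * acq$pitch_x_um / 1000
    ext_y <- ny * acq$pitch_y_um / 1000
    for (p in list(inclusion$entry_mm, inclusion$exit_mm))
      if (p[1] < 0 || p[1] > ext_x || p[2] < 0 || p[2] > ext_y)
        stop(sprintf(
          "inclusion endpoint (%.1f, %.1f) mm outside the %.1f x %.1f mm scene",
          p[1], p[2], ext_x, ext_y), call. = FALSE)
    geo <- channel_geometry(inclusion$entry_mm, inclusion$exit_mm,
                            x_mm, y_mm)
    radius <- inclusion$diameter_mm / 2
    sigma <- inclusion$blur_sigma0_mm +
      inclusion$blur_sigma_slope * geo$depth_mm
    S <- lateral_amplitude(as.vector(geo$lateral_mm), radius,
                           as.vector(sigma))
    mueff <- effective_attenuation(substrate, wl)
    Cc <- contrast_spectrum(inclusion, wl)
    # perturbation matrix, pixels x bands, built column-wise to bound
    # peak memory at the native cube size
    refl <- exp(outer(-2 * as.vector(geo$depth_mm), mueff))
    for (b in seq_len(nb))
      refl[, b] <- R0[b] * (1 + Cc[b] * S * refl[, b])
    mask <- geo$lateral_mm <= radius
    depth_map <- ifelse(mask, geo$depth_mm, -1)
    truth <- structure(list(
      depth_map = depth_map, inclusion_mask = mask,
      iso_wavelength_analytic =
        analytic_iso_wavelength(inclusion, acq$band_range_nm),
      background_spectrum = R0, along_mm = geo$along_mm,
      lateral_mm = geo$lateral_mm, axis_entry_mm = inclusion$entry_mm,
      axis_exit_mm = inclusion$exit_mm, x_mm = x_mm, y_mm = y_mm),
      class = "ground_truth")
  } else {
    refl <- matrix(rep(R0, each = npix), npix, nb)
    truth <- structure(list(
      depth_map = matrix(-1, nx, ny),
      inclusion_mask = matrix(FALSE, nx, ny),
      iso_wavelength_analytic = NA_real_, background_spectrum = R0,
      along_mm = NULL, lateral_mm = NULL, axis_entry_mm = NULL,
      axis_exit_mm = NULL, x_mm = x_mm, y_mm = y_mm),
      class = "ground_truth")
  }

  for (b in seq_len(nb)) refl[, b] <- refl[, b] * il[b]
  dim(refl) <- c(nx, ny, nb)
  kern <- spectral_psf_kernel(acq)
  if (length(kern) > 1) refl <- band_convolve(refl, kern)

  ref_frame <- array(rep(il * reference_reflectance, each = npix),
                     c(nx, ny, nb))

  if (acq$noise_sigma > 0) {
    apply_noise <- function() {
      refl <<- refl * (1 + acq$noise_sigma * stats::rnorm(length(refl)))
      ref_frame <<- ref_frame *
        (1 + acq$noise_sigma * stats::rnorm(length(ref_frame)))
    }
    if (!is.null(acq$seed)) withr::with_seed(acq$seed, apply_noise())
    else apply_noise()
    refl <- abs(refl)  # clip rare negative excursions at 1% noise
    ref_frame <- abs(ref_frame)
  }

  raw <- spectral_cube(refl, wl, acq$pitch_x_um, acq$pitch_y_um, "raw")
  reference <- spectral_cube(ref_frame, wl, acq$pitch_x_um,
                             acq$pitch_y_um, "raw")
  list(raw = raw, reference = reference, truth = truth)
}

# Gaussian kernel over band indices for the spectral PSF; collapses to
# a delta when the PSF FWHM does not exceed the band sampling.
spectral_psf_kernel <- function(acq) {
  if (acq$spectral_psf_fwhm_nm <= acq$band_sampling_nm) return(1)
  sig <- acq$spectral_psf_fwhm_nm / (2 * sqrt(2 * log(2))) /
    acq$band_sampling_nm
  half <- max(1L, ceiling(3 * sig))
  k <- exp(-0.5 * ((-half):half / sig)^2)
  k / sum(k)
}

#' Write the three canonical phantom scenes to disk
#'
#' Generates the water-filled (no iso-point), boundary-concentration
#' (contrast grazes zero) and high-concentration (clear iso-point near
#' 575 nm) scenes at desk scale and writes each as an ENVI cube pair
#' (raw + white reference) with a ground-truth CSV and a key-value
#' scene description.  Outputs are deterministic for a given seed.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed controlling all scene noise.
#' @param acq an [acquisition_spec]; default [desk_acquisition()].
#' @param noise_sigma relative noise level for all scenes.
#' @return (invisibly) a named list of the three scene directories.
#' @export
make_fixture_suite <- function(dir, seed = 1L, acq = NULL,
                               noise_sigma = 0.01) {
  if (is.null(acq)) acq <- desk_acquisition()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  base <- inclusion_geometry()
  scenes <- list(
    water = 0,
    boundary = boundary_concentration(base),
    high = 0.10)
  out <- list()
  for (i in seq_along(scenes)) {
    nm <- names(scenes)[i]
    sdir <- file.path(dir, nm)
    dir.create(sdir, showWarnings = FALSE)
    inc <- base
    inc$absorber$concentration <- scenes[[i]]
    acq_i <- acq
    acq_i$noise_sigma <- noise_sigma
    acq_i$seed <- as.integer(seed + i - 1)
    sc <- simulate_cube(medium_optics(), inc, acq_i)
    write_envi(sc$raw, file.path(sdir, "cube"))
    write_envi(sc$reference, file.path(sdir, "reference"))
    write_ground_truth(sc$truth, file.path(sdir, "ground_truth.csv"))
    write_config(list(
      scene = nm, concentration = scenes[[i]],
      iso_wavelength_analytic_nm =
        ifelse(is.na(sc$truth$iso_wavelength_analytic), "none",
               sc$truth$iso_wavelength_analytic),
      n_x = acq_i$n_x, n_y = acq_i$n_y,
      pitch_x_um = acq_i$pitch_x_um, pitch_y_um = acq_i$pitch_y_um,
      entry_x_mm = inc$entry_mm[1], entry_y_mm = inc$entry_mm[2],
      entry_depth_mm = inc$entry_mm[3],
      exit_x_mm = inc$exit_mm[1], exit_y_mm = inc$exit_mm[2],
      exit_depth_mm = inc$exit_mm[3],
      noise_sigma = noise_sigma, seed = acq_i$seed),
      file.path(sdir, "scene.cfg"))
    out[[nm]] <- sdir
  }
  invisible(out)
}
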