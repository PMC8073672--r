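#' Absorber specification
#'
#' Describes a red-transparent dye (an ink analogue) by a Gaussian
#' extinction band.  The band is parameterized by its peak wavelength,
#' full width at half maximum and peak extinction per unit concentration;
#' at 1.5 FWHM beyond the peak the extinction has fallen below 0.2% of
#' its peak value, so the red/NIR side of the spectrum is effectively
#' transparent.
#'
#' @param peak_wavelength_nm wavelength of maximum extinction, nm.
#' @param fwhm_nm full width at half maximum of the band, nm (> 0).
#' @param peak_extinction peak extinction coefficient per unit
#'   concentration, mm^-1.
#' @param concentration dye concentration as a dimensionless fraction in
#'   `[0, 1]`; 0 models a water-filled inclusion.
#' @return object of class `absorber_spec`.
#' @export
absorber_spec <- function(peak_wavelength_nm = 480, fwhm_nm = 100,
                          peak_extinction = 10, concentration = 0.10) {
  if (fwhm_nm <= 0) stop("`fwhm_nm` must be > 0", call. = FALSE)
  if (peak_extinction < 0) stop("`peak_extinction` must be >= 0", call. = FALSE)
  if (concentration < 0)
    stop("`concentration` must be nonnegative", call. = FALSE)
  structure(list(peak_wavelength_nm = peak_wavelength_nm,
                 fwhm_nm = fwhm_nm, peak_extinction = peak_extinction,
                 concentration = concentration),
            class = "absorber_spec")
}

#' Gaussian extinction curve of an absorber
#'
#' \deqn{\epsilon(\lambda) = \epsilon_{peak}\,c\,
#'   \exp\!\left(-4\ln 2\,(\lambda-\lambda_{peak})^2 / \mathrm{FWHM}^2\right)}
#'
#' @param absorber an [absorber_spec].
#' @param lambda_nm wavelength(s), nm.
#' @return extinction coefficient(s), mm^-1 (vectorized over
#'   `lambda_nm`).
#' @export
#' @examples
#' a <- absorber_spec(480, 100, 10, 0.1)
#' extinction(a, 480)        # peak: 10 * 0.1
#' extinction(a, 480 + 50)   # half the peak (FWHM definition)
extinction <- function(absorber, lambda_nm) {
  stopifnot(inherits(absorber, "absorber_spec"))
  if (absorber$concentration < 0)
    stop("negative absorber concentration", call. = FALSE)
  absorber$peak_extinction * absorber$concentration *
    exp(-4 * log(2) *
          (lambda_nm - absorber$peak_wavelength_nm)^2 / absorber$fwhm_nm^2)
}

#' Optical properties of a turbid medium
#'
#' Wavelength-resolved absorption and reduced-scattering coefficients of
#' a homogeneous turbid substrate.  Scattering follows the usual
#' power-law \eqn{\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}}; the
#' absorption is a flat background plus (optionally) the extinction band
#' of a background absorber, mirroring a phantom cast with scatterer and
#' a small amount of the same dye that fills the inclusion.
#'
#' @param mus_amplitude reduced scattering at the reference wavelength,
#'   mm^-1 (> 0).
#' @param mus_exponent scattering power-law exponent `b` (dimensionless).
#' @param mus_ref_nm reference wavelength for the power law, nm.
#' @param mua_background flat absorption background, mm^-1 (>= 0).
#' @param background_absorber optional [absorber_spec] contributing a
#'   spectral absorption band to the substrate, or `NULL`.
#' @param refractive_index substrate refractive index (>= 1).
#' @return object of class `medium_optics` with callable components
#'   `mu_a(lambda_nm)` and `mu_s_reduced(lambda_nm)`.
#' @export
medium_optics <- function(mus_amplitude = 1.0, mus_exponent = 1.2,
                          mus_ref_nm = 500, mua_background = 0.002,
                          background_absorber =
                            absorber_spec(concentration = 0.001),
                          refractive_index = 1.5) {
  if (mus_amplitude <= 0) stop("`mus_amplitude` must be > 0", call. = FALSE)
  if (mua_background < 0) stop("`mua_background` must be >= 0", call. = FALSE)
  if (refractive_index < 1)
    stop("`refractive_index` must be >= 1", call. = FALSE)
  force(background_absorber)
  obj <- list(
    mu_a = function(lambda_nm) {
      mua_background +
        if (is.null(background_absorber)) 0
        else extinction(background_absorber, lambda_nm)
    },
    mu_s_reduced = function(lambda_nm)
      mus_amplitude * (lambda_nm / mus_ref_nm)^(-mus_exponent),
    refractive_index = refractive_index)
  class(obj) <- "medium_optics"
  obj
}

# Empirical diffuse internal-reflection coefficient for a refractive
# index mismatch n_rel, and the derived boundary parameter k.
internal_reflection_k <- function(n_rel) {
  r_d <- -1.44 * n_rel^-2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + r_d) / (1 - r_d)
}

#' Diffuse reflectance of a semi-infinite turbid medium
#'
#' Closed-form diffusion-approximation reflectance under the
#' extrapolated-boundary condition:
#' \deqn{R_0 = \frac{a'}{1 + 2k(1-a') + (1 + 2k/3)\sqrt{3(1-a')}}}
#' with transport albedo \eqn{a' = \mu_s'/(\mu_s'+\mu_a)} and boundary
#' parameter \eqn{k = (1+r_d)/(1-r_d)} from the empirical polynomial
#' \eqn{r_d = -1.44 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n}.
#' `R0` is monotone increasing in the albedo, 1 in the lossless limit
#' and 0 when scattering vanishes.
#'
#' @param optics a [medium_optics].
#' @param lambda_nm wavelength(s), nm.
#' @return diffuse reflectance in `[0, 1]`, vectorized over `lambda_nm`.
#' @export
background_reflectance <- function(optics, lambda_nm) {
  stopifnot(inherits(optics, "medium_optics"))
  mua <- optics$mu_a(lambda_nm)
  mus <- optics$mu_s_reduced(lambda_nm)
  if (any(mua + mus == 0))
    stop("mu_a + mu_s' must be positive", call. = FALSE)
  if (any(mua < 0) || any(mus < 0))
    stop("negative optical coefficients", call. = FALSE)
  ap <- mus / (mus + mua)
  k <- internal_reflection_k(optics$refractive_index)
  ap / (1 + 2 * k * (1 - ap) + (1 + 2 * k / 3) * sqrt(3 * (1 - ap)))
}

#' Effective attenuation coefficient
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}, the decay rate of
#' diffuse fluence with depth.
#'
#' @inheritParams background_reflectance
#' @return mu_eff in mm^-1, vectorized over `lambda_nm`.
#' @export
effective_attenuation <- function(optics, lambda_nm) {
  stopifnot(inherits(optics, "medium_optics"))
  mua <- optics$mu_a(lambda_nm)
  mus <- optics$mu_s_reduced(lambda_nm)
  sqrt(3 * mua * (mua + mus))
}

#' Depth-sensitivity kernel of a buried perturbation
#'
#' Weight with which an inclusion under `depth_mm` of substrate perturbs
#' the surface reflectance: photons must cross the cover layer twice, so
#' \deqn{W(\lambda, d) = \exp(-2 \mu_{eff}(\lambda)\, d),}
#' strictly decreasing in depth with `W(., 0) = 1`.  This is the
#' mechanism by which an absorbing inclusion darkens the surface more
#' the closer it sits to it.
#'
#' @inheritParams background_reflectance
#' @param depth_mm cover depth(s), mm (>= 0).
#' @return weight(s) in `(0, 1]`.
#' @export
sensitivity_kernel <- function(optics, lambda_nm, depth_mm) {
  if (any(depth_mm < 0)) stop("`depth_mm` must be >= 0", call. = FALSE)
  exp(-2 * effective_attenuation(optics, lambda_nm) * depth_mm)
}
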