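#' Per-band depth sensitivity of reflectance
#'
#' Ordinary least-squares slope of reflectance versus cover depth,
#' band by band, over a set of depth-labelled spectra (e.g. pixels
#' sampled along the inclusion axis).  The sign structure of this
#' spectrum encodes the mechanism behind the iso-point: positive slopes
#' in the absorption-dominated band (inclusion darker when closer to
#' the surface), negative slopes in the scattering-dominated band
#' (inclusion brighter when closer).
#'
#' @param spectra numeric matrix, one row per observation, one column
#'   per band.
#' @param depth_mm cover depth of each row, mm; at least 3 distinct
#'   values required.
#' @param wavelengths_nm band-centre wavelengths (column axis), nm.
#' @return object of class `sensitivity_spectrum`: `wavelengths`,
#'   `slope` (mm^-1) and `se` (standard error of each slope).
#' @export
depth_sensitivity <- function(spectra, depth_mm, wavelengths_nm) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (length(depth_mm) != n)
    stop("`depth_mm` length must match the number of spectra", call. = FALSE)
  if (length(unique(depth_mm)) < 3)
    stop("need at least 3 distinct depths for a sensitivity fit",
         call. = FALSE)
  if (length(wavelengths_nm) != ncol(spectra))
    stop("`wavelengths_nm` length must match the band count", call. = FALSE)
  xc <- depth_mm - mean(depth_mm)
  sxx <- sum(xc^2)
  slope <- colSums(xc * spectra) / sxx
  fitted <- outer(xc, slope) +
    matrix(colMeans(spectra), n, ncol(spectra), byrow = TRUE)
  sse <- colSums((spectra - fitted)^2)
  se <- sqrt(pmax(sse, 0) / ((n - 2) * sxx))
  if (any(!is.finite(slope)))
    stop("non-finite sensitivity slopes (check input spectra)",
         call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths_nm),
                 slope = as.numeric(slope), se = as.numeric(se),
                 n_obs = n),
            class = "sensitivity_spectrum")
}

#' Detect the iso-point in a depth-sensitivity spectrum
#'
#' Locates the wavelength at which the reflectance-versus-depth slope
#' changes sign.  A sign change qualifies only if the slope is
#' significant (|slope| at least `tolerance` standard errors) somewhere
#' on each flank with the matching sign; the iso-point wavelength is
#' then linearly interpolated between the bracketing bands.  With no
#' qualifying sign change the result is `"boundary"` when the slope
#' dips toward zero somewhere (spectra graze each other at one
#' wavelength) and `"absent"` otherwise (e.g. a water-filled
#' inclusion, brighter than background at every band).  The dip
#' criterion has two components: a statistical one (|slope| below
#' `tolerance` standard errors, which catches grazing in noisy data)
#' and a relative one (|slope| below `dip_fraction` of the spectrum's
#' peak |slope|, which catches it in near-noise-free data where the
#' slope/SE ratio is scale invariant and never small).
#'
#' @param sens a `sensitivity_spectrum` from [depth_sensitivity()].
#' @param tolerance noise tolerance in units of the slope's standard
#'   error, default 2.
#' @param smooth_window optional running-mean window (bands) applied to
#'   the slope spectrum before detection; default 1 (none, assuming the
#'   cube was already band-averaged).
#' @param dip_fraction relative slope-magnitude threshold for the
#'   boundary classification, default 0.05.
#' @param separation_nm if several qualifying sign changes lie more
#'   than this far apart, the detection is ambiguous and an error of
#'   class `hsdepth_ambiguous_isopoint` carrying all candidate
#'   wavelengths is raised.
#' @return object of class `isopoint_result`: `status` one of
#'   `"found"`, `"boundary"`, `"absent"`; `iso_wavelength` (nm, `NA`
#'   when absent); `crossing_index`; `sensitivity` (the input).
#' @export
detect_isopoint <- function(sens, tolerance = 2, smooth_window = 1,
                            dip_fraction = 0.05, separation_nm = 20) {
  stopifnot(inherits(sens, "sensitivity_spectrum"))
  s <- sens$slope
  se <- sens$se
  wl <- sens$wavelengths
  if (any(!is.finite(s))) stop("sensitivity must be finite", call. = FALSE)
  if (smooth_window > 1) {
    arr <- array(s, c(1, 1, length(s)))
    s <- as.vector(running_band_mean_cpp(arr, 1L, 1L, length(s),
                                         as.integer(smooth_window)))
    arr <- array(se, c(1, 1, length(se)))
    se <- as.vector(running_band_mean_cpp(arr, 1L, 1L, length(se),
                                          as.integer(smooth_window))) /
      sqrt(smooth_window)
  }
  z <- ifelse(se > 0, s / se, ifelse(s == 0, 0, Inf * sign(s)))

  nz <- which(s != 0)
  cand <- list()
  if (length(nz) > 1) {
    flip <- which(sign(s[nz[-1]]) != sign(s[nz[-length(nz)]]))
    for (k in flip) {
      i <- nz[k]; j <- nz[k + 1]
      left_ok <- any(abs(z[1:i]) >= tolerance & sign(s[1:i]) == sign(s[i]))
      right_ok <- any(abs(z[j:length(s)]) >= tolerance &
                        sign(s[j:length(s)]) == sign(s[j]))
      if (left_ok && right_ok) {
        lam <- wl[i] + (wl[j] - wl[i]) * s[i] / (s[i] - s[j])
        strength <- min(max(abs(z[1:i])), max(abs(z[j:length(s)])))
        cand[[length(cand) + 1]] <- list(i = i, lambda = lam,
                                         strength = strength)
      }
    }
  }

  if (length(cand) > 0) {
    lams <- vapply(cand, `[[`, numeric(1), "lambda")
    if (length(cand) > 1 && diff(range(lams)) > separation_nm) {
      cnd <- structure(
        class = c("hsdepth_ambiguous_isopoint", "error", "condition"),
        list(message = sprintf(
               "ambiguous iso-point: %d well-separated sign changes (%s nm)",
               length(cand), paste(sprintf("%.1f", lams), collapse = ", ")),
             call = sys.call(-1), candidates = lams))
      stop(cnd)
    }
    best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "strength"))]]
    return(structure(list(status = "found", iso_wavelength = best$lambda,
                          crossing_index = best$i, sensitivity = sens),
                     class = "isopoint_result"))
  }

  dips <- min(abs(z)) < tolerance ||
    (max(abs(s)) > 0 && min(abs(s)) / max(abs(s)) < dip_fraction)
  status <- if (dips) "boundary" else "absent"
  structure(list(status = status,
                 iso_wavelength = if (status == "boundary")
                   wl[which.min(abs(s))] else NA_real_,
                 crossing_index = NA_integer_, sensitivity = sens),
            class = "isopoint_result")
}

#' @export
print.isopoint_result <- function(x, ...) {
  cat("iso-point detection:", x$status, "\n")
  if (!is.na(x$iso_wavelength))
    cat(sprintf("  wavelength: %.2f nm\n", x$iso_wavelength))
  invisible(x)
}

#' Band-ratio depth parameter
#'
#' The depth statistic
#' \deqn{d_i = 1 - I_{abs} / I_{iso},}
#' the relative reflectance deficit of an absorption-sensitive band
#' against the depth-invariant iso-point band.  Zero when the two bands
#' agree (no inclusion, after baseline handling) and monotone with
#' cover depth while the iso-point holds.
#'
#' @param I_abs reflectance at the absorption-sensitive wavelength.
#' @param I_iso reflectance at the iso-point wavelength; must be
#'   positive.  Non-positive values yield `NA` with a warning.
#' @return dimensionless depth parameter, vectorized.
#' @export
#' @examples
#' depth_parameter(0.3, 0.6)  # 0.5
depth_parameter <- function(I_abs, I_iso) {
  bad <- !is.na(I_iso) & I_iso <= 0
  if (any(bad)) {
    warning(sum(bad), " value(s) with non-positive iso-band reflectance ",
            "masked to NA", call. = FALSE)
    I_iso[bad] <- NA_real_
  }
  1 - I_abs / I_iso
}

#' Whole-image depth-parameter map
#'
#' Applies [depth_parameter()] per pixel at the bands nearest to the
#' requested wavelengths of a band-averaged reflectance cube, then
#' subtracts the median over a background (inclusion-free) region so
#' that pixels without inclusion sit at zero.
#'
#' @param cube a band-averaged reflectance [spectral_cube].
#' @param lambda_iso_nm iso-point wavelength, nm (from
#'   [detect_isopoint()] or supplied directly).
#' @param lambda_abs_nm absorption-sensitive wavelength, nm; default
#'   25 nm below the iso-point (other choices work, the iso-point is
#'   what matters).
#' @param background_region optional logical matrix (`n_x` x `n_y`)
#'   marking inclusion-free pixels for the baseline; default: the whole
#'   image.
#' @param baseline subtract the background median? Default `TRUE`.
#' @return object of class `depth_parameter_map`: `values` (`n_x` x
#'   `n_y`), `valid` mask, the band wavelengths actually used, and the
#'   subtracted `baseline`.
#' @export
depth_parameter_map <- function(cube, lambda_iso_nm,
                                lambda_abs_nm = lambda_iso_nm - 25,
                                background_region = NULL,
                                baseline = TRUE) {
  assert_cube(cube)
  ia <- band_index(cube, lambda_abs_nm)
  ii <- band_index(cube, lambda_iso_nm)
  I_abs <- cube$values[, , ia]
  I_iso <- cube$values[, , ii]
  vals <- suppressWarnings(depth_parameter(I_abs, I_iso))
  valid <- is.finite(vals)
  if (!all(valid))
    warning(sum(!valid), " pixel(s) masked (invalid band reflectance)",
            call. = FALSE)
  base <- 0
  if (baseline) {
    bg <- if (is.null(background_region)) valid
          else background_region & valid
    if (!any(bg)) stop("background region contains no valid pixel",
                       call. = FALSE)
    base <- stats::median(vals[bg])
    vals <- vals - base
  }
  structure(list(values = vals, valid = valid,
                 lambda_abs_nm = cube$wavelengths[ia],
                 lambda_iso_nm = cube$wavelengths[ii],
                 baseline = base),
            class = "depth_parameter_map")
}

#' @export
print.depth_parameter_map <- function(x, ...) {
  cat(sprintf(
    "depth_parameter_map: %d x %d pixels, bands %.1f / %.1f nm (abs/iso)\n",
    nrow(x$values), ncol(x$values), x$lambda_abs_nm, x$lambda_iso_nm))
  cat(sprintf("  baseline subtracted: %.4g; range: [%.4g, %.4g]\n",
              x$baseline, min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}
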