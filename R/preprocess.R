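#' Spatial median filter
#'
#' Per-band 2-D moving median over a square spatial neighbourhood
#' (default 5 x 5) with reflected borders, the standard scanner-noise
#' suppression step applied to both the scene cube and the white
#' reference before normalization.
#'
#' @param cube a [spectral_cube] (or bare 3-D array).
#' @param size odd window edge length in pixels, default 5.
#' @return filtered object of the same class/shape.
#' @export
median_filter <- function(cube, size = 5) {
  arr <- if (is_spectral_cube(cube)) cube$values else cube
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("input must be a spectral_cube or 3-D array", call. = FALSE)
  d <- dim(arr)
  if (d[1] < size || d[2] < size)
    stop(sprintf("spatial extent %d x %d smaller than the %d x %d window",
                 d[1], d[2], size, size), call. = FALSE)
  out <- median_filter_cpp(arr, d[1], d[2], d[3], as.integer(size))
  if (is_spectral_cube(cube)) { cube$values <- out; cube } else out
}

#' Running mean over the spectral axis
#'
#' Averages `window` neighbouring bands (centred window, reflected
#' ends) for spectral noise reduction.  At the native 0.28 nm band
#' sampling the default 20-band window spans about 6 nm, below the
#' 10 nm effective spectral resolution, so no spectral information is
#' lost.  The wavelength axis and band count are unchanged.
#'
#' @param cube a [spectral_cube] (or bare 3-D array).
#' @param window number of bands to average, `1 <= window <= n_bands`.
#' @return smoothed object of the same class/shape.
#' @export
band_average <- function(cube, window = 20) {
  arr <- if (is_spectral_cube(cube)) cube$values else cube
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("input must be a spectral_cube or 3-D array", call. = FALSE)
  d <- dim(arr)
  if (window < 1 || window > d[3])
    stop(sprintf("window (%d) must be in [1, %d]", window, d[3]),
         call. = FALSE)
  out <- running_band_mean_cpp(arr, d[1], d[2], d[3], as.integer(window))
  if (is_spectral_cube(cube)) { cube$values <- out; cube } else out
}

# Spectral PSF application (internal): convolve along the band axis.
band_convolve <- function(arr, kernel) {
  d <- dim(arr)
  band_convolve_cpp(arr, d[1], d[2], d[3], kernel)
}

#' Reference spectrum of the white standard
#'
#' @param wavelengths_nm band-centre wavelengths, nm.
#' @param intensity per-band intensity of the reflectance standard;
#'   must be positive at every band used for normalization.
#' @return object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(wavelengths_nm, intensity) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelengths_nm) != length(intensity))
    stop("wavelength and intensity lengths differ", call. = FALSE)
  structure(list(wavelengths = wavelengths_nm, intensity = intensity),
            class = "reference_spectrum")
}

#' Normalize a cube by a white-reference spectrum
#'
#' Divides every spectrum by the reference measured from a reflectance
#' standard, removing illumination and instrument response.  Both
#' inputs are expected to have been median-filtered first (pipeline
#' order: filter, then normalize, then band-average).  The reference
#' may be a single spectrum ([reference_spectrum]), a full reference
#' frame ([spectral_cube], averaged spatially to one spectrum per scan
#' line), or a bare numeric vector over bands.  Bands where the
#' reference falls below `threshold` times its own maximum are masked
#' to `NA`.
#'
#' @param cube a [spectral_cube] of raw intensities.
#' @param reference the white reference (see Details).
#' @param per_line if `TRUE` and `reference` is a cube, normalize each
#'   scan line by that line's reference spectrum; default `FALSE` (one
#'   global spectrum).
#' @param threshold relative reference level below which a band is
#'   masked, default `1e-6`.
#' @return a reflectance [spectral_cube].
#' @export
normalize_reflectance <- function(cube, reference, per_line = FALSE,
                                  threshold = 1e-6) {
  assert_cube(cube)
  d <- dim(cube$values)
  ref_line <- NULL
  if (inherits(reference, "reference_spectrum")) {
    if (length(reference$wavelengths) != d[3] ||
        any(abs(reference$wavelengths - cube$wavelengths) > 1e-6))
      stop("reference wavelength axis does not match the cube",
           call. = FALSE)
    ref <- reference$intensity
  } else if (is_spectral_cube(reference)) {
    if (length(reference$wavelengths) != d[3] ||
        any(abs(reference$wavelengths - cube$wavelengths) > 1e-6))
      stop("reference wavelength axis does not match the cube",
           call. = FALSE)
    if (per_line) {
      # mean over the scan (x) axis -> one spectrum per line y
      ref_line <- apply(reference$values, c(2, 3), mean)
    } else {
      ref <- apply(reference$values, 3, mean)
    }
  } else if (is.numeric(reference)) {
    if (length(reference) != d[3])
      stop("reference length does not match the cube's band count",
           call. = FALSE)
    ref <- as.numeric(reference)
  } else stop("unsupported reference type", call. = FALSE)

  vals <- cube$values
  if (!is.null(ref_line)) {
    bad <- ref_line < threshold * max(ref_line)
    ref_line[bad] <- NA_real_
    for (b in seq_len(d[3]))
      vals[, , b] <- vals[, , b] /
        matrix(ref_line[, b], d[1], d[2], byrow = TRUE)
  } else {
    bad <- ref < threshold * max(ref)
    ref[bad] <- NA_real_
    for (b in seq_len(d[3])) vals[, , b] <- vals[, , b] / ref[b]
  }
  out <- cube
  out$values <- vals
  out$kind <- "reflectance"
  class(out) <- "spectral_cube"
  out
}
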