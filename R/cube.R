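#' Spectral cube container
#'
#' A `spectral_cube` holds a 3-D intensity or reflectance array indexed as
#' `(x, y, band)` together with its wavelength axis (nm, strictly
#' increasing) and the physical pixel pitch of the scanner.  `x` is the
#' scan direction (the axis along which an inclusion's cover depth ramps
#' in the default phantom), `y` the line direction.
#'
#' @param values numeric 3-D array, dimensions `(n_x, n_y, n_band)`.
#'   All values must be finite.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length equal to `dim(values)[3]`.
#' @param pitch_x_um,pitch_y_um pixel pitch in micrometres along the scan
#'   (`x`) and line (`y`) directions.
#' @param kind `"raw"` for detector intensities, `"reflectance"` for
#'   reference-normalized data.
#'
#' @return An object of class `spectral_cube`: a list with elements
#'   `values`, `wavelengths`, `pitch_x_um`, `pitch_y_um`, `kind`.
#' @export
#' @examples
#' cube <- spectral_cube(array(1, c(4, 5, 3)), c(500, 510, 520))
#' dim(cube$values)
spectral_cube <- function(values, wavelengths, pitch_x_um = 260,
                          pitch_y_um = 43, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (x, y, band)", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3])
    stop("wavelength axis length (", length(wavelengths),
         ") does not match band dimension (", dim(values)[3], ")",
         call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(values)))
    stop("cube values must all be finite", call. = FALSE)
  if (kind == "reflectance" && any(values < 0, na.rm = TRUE))
    stop("reflectance cubes must be nonnegative", call. = FALSE)
  structure(list(values = values, wavelengths = wavelengths,
                 pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
                 kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "spectral_cube (%s): %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
    x$kind, d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  pixel pitch: %.0f um (x) x %.0f um (y)\n",
              x$pitch_x_um, x$pitch_y_um))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

is_spectral_cube <- function(x) inherits(x, "spectral_cube")

assert_cube <- function(x, arg = deparse(substitute(x))) {
  if (!is_spectral_cube(x))
    stop("`", arg, "` must be a spectral_cube", call. = FALSE)
  invisible(x)
}

#' Physical x/y coordinates of pixel centres
#'
#' Positions are in mm from the scene origin (pixel `[1, 1]` centre sits
#' at half a pitch from the origin).
#'
#' @param cube a [spectral_cube].
#' @return list with numeric vectors `x_mm` and `y_mm`.
#' @export
pixel_positions <- function(cube) {
  assert_cube(cube)
  d <- dim(cube$values)
  list(x_mm = (seq_len(d[1]) - 0.5) * cube$pitch_x_um / 1000,
       y_mm = (seq_len(d[2]) - 0.5) * cube$pitch_y_um / 1000)
}

#' Map a wavelength to its nearest band index
#'
#' Ties between two equally close band centres are broken toward the
#' longer wavelength.
#'
#' @param cube a [spectral_cube].
#' @param lambda_nm target wavelength in nm; must lie inside the cube's
#'   wavelength range.
#' @return integer band index.
#' @export
band_index <- function(cube, lambda_nm) {
  assert_cube(cube)
  wl <- cube$wavelengths
  if (lambda_nm < min(wl) || lambda_nm > max(wl))
    stop(sprintf("wavelength %.1f nm outside cube range [%.1f, %.1f]",
                 lambda_nm, min(wl), max(wl)), call. = FALSE)
  d <- abs(wl - lambda_nm)
  hits <- which(d <= min(d) + 1e-9)
  hits[length(hits)]  # tie -> longer wavelength
}

#' Crop a spectral cube to a spatial rectangle
#'
#' @param cube a [spectral_cube].
#' @param x0,y0 1-based indices of the rectangle's lower corner.
#' @param nx,ny rectangle extent in pixels.
#' @return a [spectral_cube] holding the spatial subset; wavelength axis
#'   and pitch metadata are preserved.
#' @export
#' @examples
#' cube <- spectral_cube(array(rnorm(60), c(4, 5, 3)), c(1, 2, 3) * 100 + 300)
#' crop_roi(cube, 2, 2, 2, 3)
crop_roi <- function(cube, x0, y0, nx, ny) {
  assert_cube(cube)
  d <- dim(cube$values)
  if (x0 < 1 || y0 < 1 || nx < 1 || ny < 1 ||
      x0 + nx - 1 > d[1] || y0 + ny - 1 > d[2])
    stop(sprintf(
      "crop rectangle [%d:%d, %d:%d] outside cube extent %d x %d",
      x0, x0 + nx - 1, y0, y0 + ny - 1, d[1], d[2]), call. = FALSE)
  out <- cube
  out$values <- cube$values[x0:(x0 + nx - 1), y0:(y0 + ny - 1), ,
                            drop = FALSE]
  out
}
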