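# Naive reference implementations and shared simulated scenes.
# The oracles are deliberately written as plain element loops so they
# stay independent of the package's compiled paths; both sides use the
# edge-duplicating reflection convention ... 1 0 | 0 1 ... n-1 | n-1 ...

reflect_index <- function(p, n) {
  # p is 0-based
  ifelse(p < 0, -p - 1, ifelse(p >= n, 2 * n - 1 - p, p))
}

naive_median_filter <- function(arr, size = 5) {
  d <- dim(arr)
  half <- size %/% 2
  out <- array(NA_real_, d)
  for (b in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        ii <- reflect_index((i - 1) + (-half:half), d[1]) + 1
        jj <- reflect_index((j - 1) + (-half:half), d[2]) + 1
        out[i, j, b] <- stats::median(arr[ii, jj, b])
      }
  out
}

naive_band_average <- function(arr, window) {
  d <- dim(arr)
  lo <- (window - 1) %/% 2
  hi <- window - 1 - lo
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    bb <- reflect_index((b - 1) + (-lo:hi), d[3]) + 1
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1]))
        out[i, j, b] <- sum(arr[i, j, bb]) / window
  }
  out
}

naive_depth_map <- function(cube, lambda_iso, lambda_abs) {
  ia <- band_index(cube, lambda_abs)
  ii <- band_index(cube, lambda_iso)
  d <- dim(cube$values)
  out <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2]))
    for (i in seq_len(d[1])) {
      denom <- cube$values[i, j, ii]
      out[i, j] <- if (is.na(denom) || denom <= 0) NA_real_
                   else 1 - cube$values[i, j, ia] / denom
    }
  out
}

# --- shared scenes (memoised: simulation is cheap but repeated) ------

.scene_cache <- new.env(parent = emptyenv())

test_scene <- function(concentration = 0.10, noise_sigma = 0, seed = 1,
                       psf = "default") {
  key <- paste(concentration, noise_sigma, seed, psf, sep = "|")
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  acq <- desk_acquisition(noise_sigma = noise_sigma,
                          seed = as.integer(seed))
  if (psf == "delta") acq$spectral_psf_fwhm_nm <- acq$band_sampling_nm
  inc <- inclusion_geometry()
  inc$absorber$concentration <- concentration
  sc <- simulate_cube(medium_optics(), inc, acq)
  sc$inclusion <- inc
  sc$acq <- acq
  .scene_cache[[key]] <- sc
  sc
}

preprocessed_scene <- function(...) {
  args <- list(...)
  key <- paste("prep", paste(unlist(args), collapse = "|"))
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sc <- do.call(test_scene, args)
  banded <- band_average(
    normalize_reflectance(median_filter(sc$raw),
                          median_filter(sc$reference)), 20)
  out <- list(scene = sc, banded = banded)
  .scene_cache[[key]] <- out
  out
}

scene_sensitivity <- function(...) {
  pp <- preprocessed_scene(...)
  truth <- pp$scene$truth
  sel <- which(truth$inclusion_mask &
                 truth$lateral_mm <= min(truth$lateral_mm) + 0.5)
  d <- dim(pp$banded$values)
  mat <- matrix(pp$banded$values, d[1] * d[2], d[3])
  depth_sensitivity(mat[sel, , drop = FALSE], truth$depth_map[sel],
                    pp$banded$wavelengths)
}
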