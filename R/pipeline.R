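#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters with their defaults;
#' entries of `config` override them (and command-line flags override
#' both).  Keys:
#' \describe{
#'   \item{cube, reference}{ENVI paths of a measured scene; when absent
#'     a scene is simulated.}
#'   \item{ground_truth, scene_config}{ground-truth CSV and scene
#'     key-value file restoring depth map and inclusion axis.}
#'   \item{concentration, noise_sigma, seed, scale}{simulator scene:
#'     fill concentration, relative noise, RNG seed, `"desk"` or
#'     `"native"` acquisition geometry.}
#'   \item{filter_size, band_window}{5 x 5 spatial median and 20-band
#'     spectral averaging window.}
#'   \item{lambda_iso, lambda_abs, lambda_abs_offset}{iso-point
#'     override (nm), absorption band override (nm), or offset of the
#'     absorption band below the detected iso-point (nm, default 25).}
#'   \item{tolerance}{iso-point detection tolerance in standard
#'     errors.}
#'   \item{inner_fraction}{central fraction of the inclusion used for
#'     the restricted calibration (default 0.6).}
#'   \item{out_dir}{artifact directory, or `NA` to skip writing.}
#' }
#'
#' @param config named list of overrides.
#' @return named list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    cube = NA, reference = NA, ground_truth = NA, scene_config = NA,
    concentration = 0.10, noise_sigma = 0.01, seed = 1L,
    scale = "desk", filter_size = 5, band_window = 20,
    lambda_iso = NA, lambda_abs = NA, lambda_abs_offset = 25,
    tolerance = 2, inner_fraction = 0.6, out_dir = NA,
    log_level = "info")
  for (k in names(config)) defaults[[k]] <- config[[k]]
  structure(defaults, class = "run_config")
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[hsdepth] ", ...)
}

# Selects depth-labelled spectra for the sensitivity fit: pixels along
# the inclusion axis (lateral distance within a quarter diameter).
axis_spectra <- function(cube, truth) {
  if (is.null(truth$lateral_mm))
    stop("ground truth carries no inclusion geometry", call. = FALSE)
  sel <- which(truth$inclusion_mask &
                 truth$lateral_mm <= min(truth$lateral_mm) + 0.5)
  d <- dim(cube$values)
  mat <- matrix(cube$values, d[1] * d[2], d[3])
  list(spectra = mat[sel, , drop = FALSE],
       depth_mm = truth$depth_map[sel])
}

# Inclusion-free pixels for the depth-map baseline: the decile of
# pixels farthest from the inclusion axis.
background_region <- function(truth) {
  if (is.null(truth$lateral_mm)) return(NULL)
  truth$lateral_mm >= stats::quantile(truth$lateral_mm, 0.9)
}

#' Run the full depth-reconstruction pipeline
#'
#' Chains the stages end to end: acquire (read ENVI or simulate a
#' phantom scene), preprocess (5 x 5 spatial median on scene and
#' reference, white-reference normalization, 20-band spectral
#' averaging), iso-point detection from depth-labelled axis spectra,
#' whole-image depth-parameter mapping, and piecewise depth
#' calibration with inversion.  When the iso-point is absent (water
#' fill) the depth-mapping stages are skipped and the report says why.
#'
#' @param config a [run_config()], a named list of overrides, or the
#'   path of a key-value config file.
#' @return (invisibly) a list of class `pipeline_result` with the
#'   stage outputs (`isopoint`, `map`, `profile`, `calibration`,
#'   `report`); the `report` element is a flat named list, also
#'   written to `out_dir/run_report.cfg` when `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  report <- list(seed = cfg$seed)
  result <- list(report = NULL)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  stage("acquire", {
    if (!is.na(cfg$cube)) {
      pipeline_log(cfg, "reading cube ", cfg$cube)
      raw <- read_envi(cfg$cube)
      reference <- if (!is.na(cfg$reference)) read_envi(cfg$reference)
                   else stop("`reference` path is required with `cube`")
      if (!is.na(cfg$ground_truth))
        truth <- read_ground_truth(
          cfg$ground_truth, raw$pitch_x_um, raw$pitch_y_um,
          config = if (!is.na(cfg$scene_config)) cfg$scene_config else NULL)
    } else {
      pipeline_log(cfg, "simulating scene (concentration ",
                   cfg$concentration, ", noise ", cfg$noise_sigma, ")")
      acq <- if (identical(cfg$scale, "native"))
        acquisition_spec(noise_sigma = cfg$noise_sigma,
                         seed = as.integer(cfg$seed))
      else desk_acquisition(noise_sigma = cfg$noise_sigma,
                            seed = as.integer(cfg$seed))
      inc <- inclusion_geometry()
      inc$absorber$concentration <- cfg$concentration
      sim <- simulate_cube(medium_optics(), inc, acq)
      raw <- sim$raw; reference <- sim$reference; truth <- sim$truth
      rm(sim)
    }
    report$n_x <- dim(raw$values)[1]
    report$n_y <- dim(raw$values)[2]
    report$n_bands <- dim(raw$values)[3]
  })

  banded <- stage("preprocess", {
    pipeline_log(cfg, "preprocess: median filter, normalize, band average")
    filt <- median_filter(raw, cfg$filter_size)
    ref_f <- median_filter(reference, cfg$filter_size)
    rm(raw, reference)
    norm <- normalize_reflectance(filt, ref_f)
    rm(filt, ref_f)
    band_average(norm, cfg$band_window)
  })

  iso <- stage("isopoint", {
    if (!is.na(cfg$lambda_iso)) {
      pipeline_log(cfg, "iso-point fixed at ", cfg$lambda_iso, " nm")
      structure(list(status = "found",
                     iso_wavelength = as.numeric(cfg$lambda_iso),
                     crossing_index = NA_integer_, sensitivity = NULL),
                class = "isopoint_result")
    } else {
      if (is.null(truth))
        stop("iso-point detection needs ground truth (or set `lambda_iso`)")
      ax <- axis_spectra(banded, truth)
      sens <- depth_sensitivity(ax$spectra, ax$depth_mm,
                                banded$wavelengths)
      detect_isopoint(sens, tolerance = cfg$tolerance)
    }
  })
  result$isopoint <- iso
  report$isopoint_status <- iso$status
  report$iso_wavelength_nm <- if (is.na(iso$iso_wavelength)) "none"
                              else iso$iso_wavelength
  if (!is.null(truth) && !is.na(truth$iso_wavelength_analytic))
    report$iso_wavelength_analytic_nm <- truth$iso_wavelength_analytic

  if (iso$status != "found") {
    report$depth_mapping <- paste0(
      "skipped: no usable iso-point (status '", iso$status,
      "'); the band-ratio depth statistic requires a depth-invariant ",
      "wavelength")
    pipeline_log(cfg, report$depth_mapping)
    result$report <- report
    finalize_pipeline(result, cfg)
    return(invisible(structure(result, class = "pipeline_result")))
  }

  map <- stage("depthmap", {
    l_iso <- iso$iso_wavelength
    l_abs <- if (!is.na(cfg$lambda_abs)) as.numeric(cfg$lambda_abs)
             else l_iso - cfg$lambda_abs_offset
    pipeline_log(cfg, sprintf("depth map at %.1f / %.1f nm (abs/iso)",
                              l_abs, l_iso))
    depth_parameter_map(banded, lambda_iso_nm = l_iso,
                        lambda_abs_nm = l_abs,
                        background_region =
                          if (is.null(truth)) NULL
                          else background_region(truth))
  })
  result$map <- map
  report$lambda_abs_nm <- map$lambda_abs_nm
  report$lambda_iso_used_nm <- map$lambda_iso_nm
  report$baseline <- map$baseline

  if (!is.null(truth) && !is.null(truth$axis_entry_mm)) {
    cal <- stage("calibrate", {
      pipeline_log(cfg, "calibrating depth parameter against true depth")
      prof <- extract_profile(map, truth, "along")
      cal_full <- segment_regimes(prof)
      prof_in <- inner_fraction(prof, cfg$inner_fraction)
      cal_in <- segment_regimes(prof_in,
                                mask_fraction = cfg$inner_fraction)
      lin_rng <- cal_in$depth_range_linear_mm
      pl <- prof_in[is.finite(prof_in$true_depth_mm) &
                      prof_in$true_depth_mm <= cal_in$breakpoint_depth_mm, ]
      pred <- suppressWarnings(invert_depth(pl$depth_param, cal_in))
      rmse_lin <- sqrt(mean((pred - pl$true_depth_mm)^2, na.rm = TRUE))
      list(profile = prof, full = cal_full, inner = cal_in,
           rmse_linear_mm = rmse_lin)
    })
    result$profile <- cal$profile
    result$calibration <- cal$inner
    result$calibration_full <- cal$full
    report$breakpoint_depth_mm <- cal$inner$breakpoint_depth_mm
    report$r2_linear <- cal$inner$r2_linear
    report$r2_exponential <- cal$inner$r2_exponential
    report$r2_piecewise_full <- cal$full$r2_total
    report$r2_piecewise_inner <- cal$inner$r2_total
    report$inner_fraction <- cfg$inner_fraction
    report$rmse_linear_regime_mm <- cal$rmse_linear_mm
  }

  result$report <- report
  finalize_pipeline(result, cfg)
  invisible(structure(result, class = "pipeline_result"))
}

finalize_pipeline <- function(result, cfg) {
  if (is.na(cfg$out_dir)) return(invisible())
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$map))
    write_depth_map(result$map, file.path(cfg$out_dir, "depth_map"))
  if (!is.null(result$profile)) {
    df <- result$profile
    utils::write.csv(df, file.path(cfg$out_dir, "profile_along.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$calibration))
    write_calibration(result$calibration,
                      file.path(cfg$out_dir, "calibration"))
  write_config(result$report, file.path(cfg$out_dir, "run_report.cfg"))
  invisible()
}

#' Serialize a calibration result
#'
#' Writes `<path>.cfg` (key-value report) and `<path>.csv`
#' (machine-readable single-row table).
#'
#' @param cal a `calibration_result`.
#' @param path output path without extension.
#' @return (invisibly) the path.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_result"))
  flat <- list(
    breakpoint_depth_mm = cal$breakpoint_depth_mm,
    linear_slope = if (is.null(cal$linear)) NA else cal$linear$slope,
    linear_intercept = if (is.null(cal$linear)) NA
                       else cal$linear$intercept,
    exp_amplitude = if (is.null(cal$exponential)) NA
                    else cal$exponential$amplitude,
    exp_rate = if (is.null(cal$exponential)) NA
               else cal$exponential$rate,
    exp_offset = if (is.null(cal$exponential)) NA
                 else cal$exponential$offset,
    r2_linear = cal$r2_linear, r2_exponential = cal$r2_exponential,
    r2_total = cal$r2_total, mask_fraction = cal$mask_fraction)
  write_config(flat, paste0(path, ".cfg"))
  utils::write.csv(as.data.frame(flat), paste0(path, ".csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read back a depth-parameter map written by [write_depth_map()]
#'
#' @param path path without extension.
#' @return a `depth_parameter_map`.
#' @export
read_depth_map <- function(path) {
  cube <- read_envi(path)
  cfg <- read_config(paste0(path, "_bands.cfg"))
  vals <- cube$values[, , 1]
  vals[vals == cfg$nodata] <- NA_real_
  structure(list(values = vals, valid = is.finite(vals),
                 lambda_abs_nm = cfg$lambda_abs_nm,
                 lambda_iso_nm = cfg$lambda_iso_nm,
                 baseline = cfg$baseline),
            class = "depth_parameter_map")
}
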