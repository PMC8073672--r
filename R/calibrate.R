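#' Extract a depth-parameter profile along or across the inclusion
#'
#' Samples the depth-parameter map along the inclusion axis (depth
#' ramp) or perpendicular to it, pairing every sample with the
#' ground-truth cover depth.  Positions are in mm: arc length from the
#' axis entry point (along), or signed lateral distance from the axis
#' (across, at the along-position given by `offset_mm`).
#'
#' @param map a `depth_parameter_map`.
#' @param truth a `ground_truth` from [simulate_cube()] (must carry the
#'   axis geometry).
#' @param axis `"along"` or `"across"`.
#' @param offset_mm lateral offset of an along-profile from the axis, or
#'   the along-position of an across-profile, mm.
#' @return a `depth_profile` data frame with columns `position_mm`,
#'   `depth_param`, `true_depth_mm` (`NA` outside the inclusion).
#'   Raises an error of class `hsdepth_empty_profile` when the sampled
#'   line never meets the inclusion mask.
#' @export
extract_profile <- function(map, truth, axis = c("along", "across"),
                            offset_mm = 0) {
  axis <- match.arg(axis)
  stopifnot(inherits(map, "depth_parameter_map"),
            inherits(truth, "ground_truth"))
  if (is.null(truth$axis_entry_mm))
    stop("ground truth carries no inclusion axis", call. = FALSE)
  p0 <- truth$axis_entry_mm[1:2]
  p1 <- truth$axis_exit_mm[1:2]
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  dirv <- v / len
  nrm <- c(-dirv[2], dirv[1])
  step <- min(diff(truth$x_mm[1:2]), diff(truth$y_mm[1:2]))
  if (axis == "along") {
    pos <- seq(0, len, by = step)
    pts <- cbind(p0[1] + pos * dirv[1] + offset_mm * nrm[1],
                 p0[2] + pos * dirv[2] + offset_mm * nrm[2])
  } else {
    half <- max(abs(c(truth$x_mm, truth$y_mm)))
    pos <- seq(-half, half, by = step)
    c0 <- p0 + offset_mm * dirv
    pts <- cbind(c0[1] + pos * nrm[1], c0[2] + pos * nrm[2])
  }
  ix <- round(pts[, 1] / diff(truth$x_mm[1:2]) + 0.5)
  iy <- round(pts[, 2] / diff(truth$y_mm[1:2]) + 0.5)
  keep <- ix >= 1 & ix <= length(truth$x_mm) &
    iy >= 1 & iy <= length(truth$y_mm)
  # drop repeated hits of the same pixel so positions stay informative
  pid <- ix + iy * (length(truth$x_mm) + 1)
  keep <- keep & !duplicated(pid)
  if (!any(keep))
    stop(structure(class = c("hsdepth_empty_profile", "error", "condition"),
                   list(message = "profile line lies outside the scene",
                        call = sys.call(-1))))
  ix <- ix[keep]; iy <- iy[keep]; pos <- pos[keep]
  lin <- cbind(ix, iy)
  in_mask <- truth$inclusion_mask[lin]
  if (!any(in_mask))
    stop(structure(class = c("hsdepth_empty_profile", "error", "condition"),
                   list(message = "profile line never meets the inclusion",
                        call = sys.call(-1))))
  out <- data.frame(position_mm = pos,
                    depth_param = map$values[lin],
                    true_depth_mm = ifelse(in_mask, truth$depth_map[lin],
                                           NA_real_))
  out <- out[order(out$position_mm), ]
  rownames(out) <- NULL
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Restrict a profile to its central fraction
#'
#' Keeps the central `fraction` of samples along the profile, trimming
#' `floor(n * (1 - fraction) / 2)` samples from each end.  Used to drop
#' the inclusion boundaries, where the band-ratio statistic is least
#' reliable.
#'
#' @param profile a `depth_profile`.
#' @param fraction central fraction to retain, in `(0, 1]`; default 0.6.
#' @return the trimmed `depth_profile`.
#' @export
#' @examples
#' p <- structure(data.frame(position_mm = 1:10, depth_param = 0,
#'                           true_depth_mm = 1:10),
#'                class = c("depth_profile", "data.frame"))
#' nrow(inner_fraction(p, 0.6))  # middle 6 of 10
inner_fraction <- function(profile, fraction = 0.6) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be a single value in (0, 1]", call. = FALSE)
  n <- nrow(profile)
  trim <- floor(n * (1 - fraction) / 2)
  if (trim == 0) return(profile)
  out <- profile[(trim + 1):(n - trim), ]
  rownames(out) <- NULL
  class(out) <- class(profile)
  out
}

profile_xy <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("depth_param", "true_depth_mm") %in% names(profile)))
  ok <- is.finite(profile$true_depth_mm) & is.finite(profile$depth_param)
  list(d = profile$true_depth_mm[ok], y = profile$depth_param[ok])
}

r_squared <- function(y, resid) {
  sst <- sum((y - mean(y))^2)
  sse <- sum(resid^2)
  # constant response: define r2 = 0 (SST = SSE up to round-off)
  if (sst <= .Machine$double.eps * max(1, sum(y^2))) return(0)
  1 - sse / sst
}

#' Linear depth calibration
#'
#' Ordinary least squares of the depth parameter on true depth,
#' `d_i = slope * depth + intercept`, for the shallow (linear) regime.
#'
#' @param profile a `depth_profile` (rows without ground-truth depth
#'   are ignored).
#' @return list with `slope`, `intercept`, `r2`, `sse`, `n`,
#'   `se_slope`.
#' @export
fit_linear <- function(profile) {
  xy <- profile_xy(profile)
  if (length(xy$d) < 3 || length(unique(xy$d)) < 2)
    stop("need >= 3 samples with non-constant depth for a linear fit",
         call. = FALSE)
  fit <- stats::lm(y ~ d, data = xy)
  co <- stats::coef(fit)
  sse <- sum(stats::resid(fit)^2)
  n <- length(xy$d)
  sxx <- sum((xy$d - mean(xy$d))^2)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r2 = r_squared(xy$y, stats::resid(fit)), sse = sse, n = n,
       se_slope = sqrt(sse / ((n - 2) * sxx)))
}

#' Exponential depth calibration
#'
#' Least-squares fit of `d_i = amplitude * exp(-rate * depth) + offset`
#' for the deep regime, where the iso-point degrades and the depth
#' parameter decays.  Initialization is deterministic: the offset is
#' guessed as the minimum depth parameter minus a small margin, then a
#' log-linear regression supplies amplitude and rate, refined by
#' Levenberg-Marquardt ([minpack.lm::nlsLM]) with `rate` constrained
#' nonnegative.  Depth-independent (constant) data is reported as
#' degenerate: only `amplitude + offset` is identifiable.
#'
#' @param profile a `depth_profile`.
#' @return list with `amplitude`, `rate` (mm^-1), `offset`, `r2`,
#'   `sse`, `n`, `degenerate`.  Non-convergence raises an error of
#'   class `hsdepth_fit_failure` carrying the optimizer diagnostics.
#' @export
fit_exponential <- function(profile) {
  xy <- profile_xy(profile)
  d <- xy$d; y <- xy$y
  if (length(d) < 4)
    stop("need >= 4 samples for an exponential fit", call. = FALSE)
  rng <- diff(range(y))
  if (rng < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    return(list(amplitude = 0, rate = 0, offset = mean(y), r2 = 0,
                sse = sum((y - mean(y))^2), n = length(d),
                degenerate = TRUE))
  }
  c0 <- min(y) - 0.05 * rng
  ly <- log(y - c0)
  ll <- stats::lm(ly ~ d)
  k0 <- max(-unname(stats::coef(ll)[2]), 1e-6)
  a0 <- exp(unname(stats::coef(ll)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-k * d) + C,
      data = data.frame(d = d, y = y),
      start = list(A = a0, k = k0, C = c0),
      lower = c(A = -Inf, k = 0, C = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(structure(class = c("hsdepth_fit_failure", "error", "condition"),
                   list(message = paste("exponential fit failed:",
                                        conditionMessage(fit)),
                        call = sys.call(-1), diagnostics = fit)))
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  list(amplitude = unname(co["A"]), rate = unname(co["k"]),
       offset = unname(co["C"]), r2 = r_squared(y, res),
       sse = sum(res^2), n = length(d), degenerate = FALSE)
}

#' Piecewise linear/exponential depth calibration
#'
#' Segments a depth-parameter profile into the shallow linear regime
#' and the deep exponential regime by a grid search over candidate
#' breakpoints at the profile's own depth resolution: for each
#' candidate, a linear fit below and an exponential fit above are
#' combined and the breakpoint minimizing the total sum of squared
#' errors wins (ties go to the smaller breakpoint).  Degenerate
#' candidates with one empty segment are included, so the piecewise SSE
#' never exceeds either single-model fit; a profile that is exactly
#' linear everywhere yields the maximal breakpoint with the exponential
#' segment flagged empty.
#'
#' @param profile a `depth_profile`.
#' @param min_linear,min_exp minimum samples per segment (3 and 4).
#' @param max_candidates cap on the breakpoint grid; above it the grid
#'   is thinned to depth quantiles.
#' @param mask_fraction recorded central-fraction restriction applied
#'   to the profile before calling (bookkeeping only), default 1.
#' @return object of class `calibration_result`: `breakpoint_depth_mm`,
#'   `linear` and `exponential` fit components (either may be `NULL`
#'   when its segment is empty), `r2_linear`, `r2_exponential`,
#'   `r2_total` (explained variance of the piecewise model on the whole
#'   profile), `sse_total`, segment depth ranges, `mask_fraction`.
#' @export
segment_regimes <- function(profile, min_linear = 3, min_exp = 4,
                            max_candidates = 200, mask_fraction = 1) {
  xy <- profile_xy(profile)
  d <- xy$d; y <- xy$y
  if (length(d) < min_linear + 1)
    stop("profile too short for regime segmentation", call. = FALSE)
  dd <- sort(unique(d))
  sst <- sum((y - mean(y))^2)
  prof_all <- new_profile(d, y)

  # exactly linear data: single-branch shortcut
  lin_all <- fit_linear(prof_all)
  if (lin_all$sse <= max(1e-12 * sst, 1e-20))
    return(new_calibration(max(d), lin_all, NULL, y, lin_all$sse,
                           range(d), c(NA, NA), mask_fraction))

  cands <- dd
  if (length(cands) > max_candidates)
    cands <- unique(stats::quantile(dd, probs =
      seq(0, 1, length.out = max_candidates), names = FALSE, type = 1))
  best <- NULL
  for (bp in c(cands, min(d) - 1e-9)) {   # last: empty linear segment
    lo <- d <= bp
    hi <- !lo
    fl <- NULL; fe <- NULL
    sse <- 0
    if (sum(lo) > 0) {
      if (sum(lo) < min_linear || length(unique(d[lo])) < 2) next
      fl <- tryCatch(fit_linear(new_profile(d[lo], y[lo])),
                     error = function(e) NULL)
      if (is.null(fl)) next
      sse <- sse + fl$sse
    }
    if (sum(hi) > 0) {
      if (sum(hi) < min_exp) next
      fe <- tryCatch(fit_exponential(new_profile(d[hi], y[hi])),
                     error = function(e) NULL)
      if (is.null(fe)) next
      sse <- sse + fe$sse
    }
    bp_eff <- min(max(bp, min(d)), max(d))
    if (is.null(best) || sse < best$sse * (1 - 1e-9) ||
        (abs(sse - best$sse) <= 1e-9 * max(best$sse, 1e-300) &&
         bp_eff < best$bp))
      best <- list(bp = bp_eff, lin = fl, ex = fe, sse = sse,
                   rng_lin = if (any(lo)) range(d[lo]) else c(NA, NA),
                   rng_exp = if (any(hi)) range(d[hi]) else c(NA, NA))
  }
  if (is.null(best))
    stop("no breakpoint leaves enough samples in both regimes",
         call. = FALSE)
  new_calibration(best$bp, best$lin, best$ex, y, best$sse,
                  best$rng_lin, best$rng_exp, mask_fraction)
}

new_profile <- function(d, y) {
  structure(data.frame(position_mm = d, depth_param = y,
                       true_depth_mm = d),
            class = c("depth_profile", "data.frame"))
}

new_calibration <- function(bp, lin, ex, y_all, sse, rng_lin, rng_exp,
                            mask_fraction) {
  sst <- sum((y_all - mean(y_all))^2)
  structure(list(
    breakpoint_depth_mm = bp, linear = lin, exponential = ex,
    r2_linear = if (is.null(lin)) NA_real_ else lin$r2,
    r2_exponential = if (is.null(ex)) NA_real_ else ex$r2,
    r2_total = if (sst > 0) 1 - sse / sst else 0,
    sse_total = sse, depth_range_linear_mm = rng_lin,
    depth_range_exp_mm = rng_exp, mask_fraction = mask_fraction),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("piecewise depth calibration (inner fraction %.0f%%)\n",
              100 * x$mask_fraction))
  cat(sprintf("  breakpoint: %.2f mm; piecewise R2 = %.4f\n",
              x$breakpoint_depth_mm, x$r2_total))
  if (!is.null(x$linear))
    cat(sprintf("  linear  : d_i = %.4g * d + %.4g   (R2 = %.4f)\n",
                x$linear$slope, x$linear$intercept, x$r2_linear))
  if (!is.null(x$exponential))
    cat(sprintf(
      "  exponent: d_i = %.4g * exp(-%.4g d) + %.4g   (R2 = %.4f)\n",
      x$exponential$amplitude, x$exponential$rate,
      x$exponential$offset, x$r2_exponential))
  invisible(x)
}

#' Invert the depth calibration
#'
#' Maps depth-parameter values back to physical depth: the linear
#' branch is inverted in closed form, the exponential branch through a
#' logarithm.  Each value is assigned to the branch whose calibrated
#' depth range it lands in (linear first).  The mapping is only
#' piecewise injective — like `y = x^2`, one depth-parameter value can
#' be reachable from both regimes; the linear (shallow) branch is
#' preferred, and values reachable by neither branch yield `NA` with a
#' warning.
#'
#' @param d_i depth-parameter value(s).
#' @param calibration a `calibration_result`.
#' @param slack_mm how far beyond a branch's calibrated depth range an
#'   inverted depth may fall before it is rejected, mm.
#' @return depth(s) in mm, `NA` where out of range.
#' @export
invert_depth <- function(d_i, calibration, slack_mm = 0.5) {
  stopifnot(inherits(calibration, "calibration_result"))
  out <- rep(NA_real_, length(d_i))
  lin <- calibration$linear
  ex <- calibration$exponential
  rl <- calibration$depth_range_linear_mm
  re <- calibration$depth_range_exp_mm
  if (!is.null(lin) && lin$slope != 0 && all(is.finite(rl))) {
    cand <- (d_i - lin$intercept) / lin$slope
    ok <- is.na(out) & cand >= rl[1] - slack_mm & cand <= rl[2] + slack_mm
    out[ok] <- cand[ok]
  }
  if (!is.null(ex) && !isTRUE(ex$degenerate) && ex$rate > 0 &&
      all(is.finite(re))) {
    arg <- (d_i - ex$offset) / ex$amplitude
    cand <- ifelse(arg > 0, -log(arg) / ex$rate, NA_real_)
    ok <- is.na(out) & !is.na(cand) &
      cand >= re[1] - slack_mm & cand <= re[2] + slack_mm
    out[ok] <- cand[ok]
  }
  if (anyNA(out))
    warning(sum(is.na(out)),
            " depth-parameter value(s) outside the calibrated range",
            call. = FALSE)
  out
}
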