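#' Write a spectral cube in ENVI format
#'
#' Band-sequential (BSQ) interleave, 32-bit little-endian IEEE floats,
#' with a text header carrying the dimensions and the wavelength list
#' in nm.  `samples` maps to the scan (`x`) axis and `lines` to the
#' line (`y`) axis.  Output bytes are deterministic for identical
#' input.
#'
#' @param cube a [spectral_cube].
#' @param path output path without extension; `<path>.dat` and
#'   `<path>.hdr` are written.
#' @return (invisibly) the data-file path.
#' @export
write_envi <- function(cube, path) {
  assert_cube(cube)
  d <- dim(cube$values)
  if (any(d == 0) || length(cube$values) == 0)
    stop("refusing to write an empty cube", call. = FALSE)
  hdr <- c(
    "ENVI",
    "description = {hsdepth spectral cube}",
    paste0("samples = ", d[1]),
    paste0("lines = ", d[2]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("pixel size = {", cube$pitch_x_um, ", ", cube$pitch_y_um, "}"),
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(formatC(cube$wavelengths, format = "g", digits = 15),
                 collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(cube$values), con, size = 4, endian = "little")
  invisible(paste0(path, ".dat"))
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # key = value, where value may be a {...} block spanning lines
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("not an ENVI header: ", hdr_path, call. = FALSE)
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

envi_num <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI header missing field '", key, "'",
                       call. = FALSE)
  as.numeric(v)
}

#' Read an ENVI-format spectral cube
#'
#' Handles BSQ, BIL and BIP interleaves, 32-bit float (data type 4) and
#' 64-bit float (data type 5), little- or big-endian.  The header's
#' wavelength list becomes the cube's wavelength axis; its length must
#' match the band count.
#'
#' @param path path to the cube without extension, or to either the
#'   `.hdr` or the data file.
#' @return a [spectral_cube].
#' @export
read_envi <- function(path) {
  base <- sub("\\.(hdr|dat|img|bin)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  dat_path <- NULL
  for (ext in c(".dat", ".img", ".bin", ""))
    if (file.exists(paste0(base, ext)) && !dir.exists(paste0(base, ext))) {
      dat_path <- paste0(base, ext); break
    }
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path, call. = FALSE)
  if (is.null(dat_path))
    stop("ENVI data file not found for ", base, call. = FALSE)
  f <- parse_envi_header(hdr_path)
  ns <- envi_num(f, "samples"); nl <- envi_num(f, "lines")
  nb <- envi_num(f, "bands")
  dtype <- envi_num(f, "data type")
  if (!dtype %in% c(4, 5))
    stop("unsupported ENVI data type ", dtype,
         " (only 4 = float32, 5 = float64)", call. = FALSE)
  sz <- if (dtype == 4) 4L else 8L
  endian <- if (!is.null(f[["byte order"]]) &&
                envi_num(f, "byte order") == 1) "big" else "little"
  interleave <- tolower(if (is.null(f[["interleave"]])) "bsq"
                        else f[["interleave"]])
  wl_raw <- f[["wavelength"]]
  if (is.null(wl_raw))
    stop("ENVI header has no 'wavelength' list", call. = FALSE)
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf(
      "ENVI header field 'wavelength' has %d entries but 'bands' = %d",
      length(wl), nb), call. = FALSE)
  n_total <- ns * nl * nb
  expected <- n_total * sz + envi_num_or(f, "header offset", 0)
  if (file.size(dat_path) < expected)
    stop(sprintf(
      "ENVI data file too small: %d bytes, need %d from 'samples/lines/bands'",
      file.size(dat_path), expected), call. = FALSE)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  off <- envi_num_or(f, "header offset", 0)
  if (off > 0) readBin(con, "raw", n = off)
  v <- readBin(con, "numeric", n = n_total, size = sz, endian = endian)
  arr <- switch(interleave,
    bsq = array(v, c(ns, nl, nb)),
    bil = aperm(array(v, c(ns, nb, nl)), c(1, 3, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(2, 3, 1)),
    stop("unsupported interleave '", interleave, "'", call. = FALSE))
  pitch <- c(260, 43)
  if (!is.null(f[["pixel size"]])) {
    p <- as.numeric(strsplit(gsub("[{}]", "", f[["pixel size"]]),
                             ",")[[1]])
    if (length(p) == 2 && all(is.finite(p))) pitch <- p
  }
  spectral_cube(arr, wl, pitch[1], pitch[2], "raw")
}

envi_num_or <- function(fields, key, default) {
  if (is.null(fields[[key]])) default else as.numeric(fields[[key]])
}

#' Read/write a white-reference spectrum as CSV
#'
#' Two columns: `wavelength_nm`, `intensity`.
#'
#' @param ref a [reference_spectrum] (for writing).
#' @param path CSV path.
#' @return `read_reference_csv` returns a [reference_spectrum];
#'   `write_reference_csv` the path, invisibly.
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = ref$wavelengths,
                              intensity = ref$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("reference CSV needs columns wavelength_nm, intensity",
         call. = FALSE)
  reference_spectrum(df$wavelength_nm, df$intensity)
}

#' Read/write per-pixel ground truth as CSV
#'
#' Columns: `x`, `y` (0-based pixel indices), `depth_mm` (cover depth;
#' -1 outside the inclusion) and `in_inclusion` (0/1).
#'
#' @param truth a `ground_truth` (for writing).
#' @param path CSV path.
#' @param pitch_x_um,pitch_y_um pixel pitch used to restore physical
#'   coordinates when reading.
#' @return `read_ground_truth` returns a `ground_truth` (without axis
#'   geometry unless supplied via `config`); `write_ground_truth` the
#'   path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- dim(truth$depth_map)
  df <- data.frame(
    x = rep(seq_len(d[1]) - 1L, times = d[2]),
    y = rep(seq_len(d[2]) - 1L, each = d[1]),
    depth_mm = as.vector(truth$depth_map),
    in_inclusion = as.integer(as.vector(truth$inclusion_mask)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @param config optional scene config (list or path readable by
#'   [read_config()]) restoring the analytic iso-point wavelength and
#'   the inclusion axis.
#' @export
read_ground_truth <- function(path, pitch_x_um = 260, pitch_y_um = 43,
                              config = NULL) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "depth_mm", "in_inclusion")
  if (!all(need %in% names(df)))
    stop("ground-truth CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  nx <- max(df$x) + 1L; ny <- max(df$y) + 1L
  depth <- matrix(NA_real_, nx, ny)
  mask <- matrix(FALSE, nx, ny)
  idx <- cbind(df$x + 1L, df$y + 1L)
  depth[idx] <- df$depth_mm
  mask[idx] <- df$in_inclusion == 1
  cfg <- if (is.character(config)) read_config(config) else config
  iso <- NA_real_
  entry <- exit <- NULL
  if (!is.null(cfg)) {
    if (!is.null(cfg$iso_wavelength_analytic_nm) &&
        !identical(cfg$iso_wavelength_analytic_nm, "none"))
      iso <- as.numeric(cfg$iso_wavelength_analytic_nm)
    if (!is.null(cfg$pitch_x_um)) pitch_x_um <- cfg$pitch_x_um
    if (!is.null(cfg$pitch_y_um)) pitch_y_um <- cfg$pitch_y_um
    if (!is.null(cfg$entry_x_mm))
      entry <- c(cfg$entry_x_mm, cfg$entry_y_mm, cfg$entry_depth_mm)
    if (!is.null(cfg$exit_x_mm))
      exit <- c(cfg$exit_x_mm, cfg$exit_y_mm, cfg$exit_depth_mm)
  }
  x_mm <- (seq_len(nx) - 0.5) * pitch_x_um / 1000
  y_mm <- (seq_len(ny) - 0.5) * pitch_y_um / 1000
  along <- lateral <- NULL
  if (!is.null(entry) && !is.null(exit)) {
    geo <- channel_geometry(entry, exit, x_mm, y_mm)
    along <- geo$along_mm
    lateral <- geo$lateral_mm
  }
  structure(list(depth_map = depth, inclusion_mask = mask,
                 iso_wavelength_analytic = iso,
                 background_spectrum = NULL, along_mm = along,
                 lateral_mm = lateral, axis_entry_mm = entry,
                 axis_exit_mm = exit, x_mm = x_mm, y_mm = y_mm),
            class = "ground_truth")
}

#' Flat key-value configuration files
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored.  Values that parse as numbers are returned numeric.
#'
#' @param x named list (for writing).
#' @param path file path.
#' @return `read_config` returns a named list; `write_config` the
#'   path, invisibly.
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(k)
    paste0(k, " = ", format(x[[k]], digits = 15, scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln)) next
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a depth-parameter map to disk
#'
#' The map is written both as a single-band ENVI frame (float32) and as
#' a CSV (`x`, `y`, `depth_param`), next to a small key-value report of
#' the bands used.
#'
#' @param map a `depth_parameter_map`.
#' @param path output path without extension.
#' @return (invisibly) the path.
#' @export
write_depth_map <- function(map, path) {
  stopifnot(inherits(map, "depth_parameter_map"))
  d <- dim(map$values)
  vals <- map$values
  vals[!is.finite(vals)] <- -9999
  cube <- spectral_cube(array(vals, c(d[1], d[2], 1)),
                        map$lambda_iso_nm, kind = "raw")
  write_envi(cube, path)
  df <- data.frame(x = rep(seq_len(d[1]) - 1L, times = d[2]),
                   y = rep(seq_len(d[2]) - 1L, each = d[1]),
                   depth_param = as.vector(map$values))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  write_config(list(lambda_abs_nm = map$lambda_abs_nm,
                    lambda_iso_nm = map$lambda_iso_nm,
                    baseline = map$baseline,
                    nodata = -9999),
               paste0(path, "_bands.cfg"))
  invisible(path)
}
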