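## File formats: NIfTI is the primary image container (pixel spacing and
## frame interval travel in the header, doubles round-trip exactly);
## multi-page TIFF is provided for portability with a YAML sidecar
## carrying the metadata and the intensity normalisation (TIFF float
## storage is only defined on [0, 1]).

has_ext <- function(path, exts) {
  low <- tolower(path)
  any(vapply(exts, function(e) endsWith(low, e), logical(1)))
}

tiff_sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an image series to NIfTI or multi-page TIFF
#'
#' NIfTI (`.nii`, `.nii.gz`) stores doubles with pixel spacing and frame
#' interval in the header and round-trips bit-exactly. TIFF (`.tif`,
#' `.tiff`) stores 32-bit floats normalised to `[0, 1]`, with the
#' normalisation and metadata in a YAML sidecar next to the file.
#'
#' @param series an [image_series()]
#' @param path output path; format chosen by extension
#' @return `path`, invisibly
#' @export
write_image_series <- function(series, path) {
  check_that(inherits(series, "image_series"), "write_image_series: not an image_series")
  d <- dim(series$data)
  if (has_ext(path, c(".nii", ".nii.gz"))) {
    hdr <- RNifti::niftiHeader(list(
      dim = c(3L, d[1], d[2], d[3], 1L, 1L, 1L, 1L),
      pixdim = c(1, series$pixel_spacing_mm, series$pixel_spacing_mm,
                 series$frame_interval_s, 0, 0, 0, 0),
      datatype = 64L))
    img <- RNifti::asNifti(series$data, reference = hdr, datatype = "double")
    RNifti::writeNifti(img, path)
  } else if (has_ext(path, c(".tif", ".tiff"))) {
    lo <- min(series$data); hi <- max(series$data)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3]), function(t)
      (series$data[, , t] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    yaml::write_yaml(list(pixel_spacing_mm = series$pixel_spacing_mm,
                          frame_interval_s = series$frame_interval_s,
                          intensity_offset = lo, intensity_scale = scale),
                     tiff_sidecar_path(path))
  } else stop("write_image_series: unsupported extension (use .nii[.gz] or .tif[f])",
              call. = FALSE)
  invisible(path)
}

#' Read an image series from NIfTI or multi-page TIFF
#'
#' Diameters are measured in mm, so the pixel spacing must be present:
#' a NIfTI header with non-positive spatial or temporal pixdim, or a TIFF
#' without its YAML sidecar, is a hard error naming the missing field.
#'
#' @param path input path
#' @return an [image_series()]
#' @export
read_image_series <- function(path) {
  if (has_ext(path, c(".nii", ".nii.gz"))) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3 || pd[1] <= 0 || pd[2] <= 0)
      stop("read_image_series: missing or non-positive pixel spacing (pixdim) in NIfTI header",
           call. = FALSE)
    if (pd[3] <= 0)
      stop("read_image_series: missing or non-positive frame interval (pixdim[4]) in NIfTI header",
           call. = FALSE)
    if (abs(pd[1] - pd[2]) > 1e-6)
      stop("read_image_series: anisotropic pixel spacing is not supported",
           call. = FALSE)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    image_series(arr, pd[1], pd[3])
  } else if (has_ext(path, c(".tif", ".tiff"))) {
    side <- tiff_sidecar_path(path)
    if (!file.exists(side))
      stop("read_image_series: TIFF carries no spacing metadata; sidecar file '",
           side, "' with field pixel_spacing_mm is required", call. = FALSE)
    meta <- yaml::read_yaml(side)
    for (field in c("pixel_spacing_mm", "frame_interval_s"))
      if (is.null(meta[[field]]))
        stop("read_image_series: sidecar is missing field '", field, "'",
             call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    lo <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
    sc <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * sc + lo
    image_series(arr, meta$pixel_spacing_mm, meta$frame_interval_s)
  } else stop("read_image_series: unsupported extension", call. = FALSE)
}

#' Write a pressure recording as CSV plus YAML sidecar
#'
#' The CSV has a `time_s` column followed by one column per channel
#' (`ch1..chN`, proximal to distal); sensor positions, sampling rate,
#' units and the distal direction convention go in the sidecar.
#'
#' @param rec a [pressure_recording()]
#' @param path CSV output path
#' @param sidecar_path YAML sidecar path (default: `path` + `.yaml`)
#' @return `path`, invisibly
#' @export
write_pressure_csv <- function(rec, path,
                               sidecar_path = paste0(path, ".yaml")) {
  check_that(inherits(rec, "pressure_recording"), "write_pressure_csv: not a pressure_recording")
  df <- data.frame(time_s = rec$times_s, t(rec$pressure_mmhg))
  names(df) <- c("time_s", rec$labels)
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(channel_positions_mm = rec$channel_positions_mm,
                        sampling_rate_hz = rec$sampling_rate_hz,
                        units = "mmHg",
                        distal_direction = "increasing",
                        labels = rec$labels),
                   sidecar_path)
  invisible(path)
}

#' Read a pressure recording from CSV plus YAML sidecar
#'
#' Validates that the sidecar channel positions match the CSV channel
#' count, that the time column is strictly increasing and regular, and
#' that the declared distal direction is increasing channel index.
#'
#' @param path CSV path (`time_s`, then one column per channel)
#' @param sidecar_path YAML sidecar path
#' @return a [pressure_recording()]
#' @export
read_pressure_csv <- function(path, sidecar_path = paste0(path, ".yaml")) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_that("time_s" %in% names(df),
             "read_pressure_csv: CSV must have a time_s column")
  meta <- yaml::read_yaml(sidecar_path)
  for (field in c("channel_positions_mm", "sampling_rate_hz"))
    if (is.null(meta[[field]]))
      stop("read_pressure_csv: sidecar is missing field '", field, "'",
           call. = FALSE)
  n_ch <- ncol(df) - 1
  if (length(meta$channel_positions_mm) != n_ch)
    stop(sprintf("read_pressure_csv: sidecar lists %d channel positions but CSV has %d channels",
                 length(meta$channel_positions_mm), n_ch), call. = FALSE)
  tm <- df$time_s
  check_that(all(diff(tm) > 0), "read_pressure_csv: time column must be strictly increasing")
  if (length(tm) > 2)
    check_that(max(abs(diff(diff(tm)))) < 1e-6,
               "read_pressure_csv: time column must be regularly sampled")
  if (!is.null(meta$distal_direction) &&
      !identical(meta$distal_direction, "increasing"))
    stop("read_pressure_csv: distal_direction must be 'increasing' (proximal-to-distal channel order)",
         call. = FALSE)
  pressure_recording(t(as.matrix(df[, -1, drop = FALSE])),
                     meta$sampling_rate_hz,
                     unlist(meta$channel_positions_mm),
                     labels = names(df)[-1])
}

#' Write contraction events or HAPCs as JSON
#'
#' Times are in seconds, amplitudes in mmHg, velocities in mm/s; windows
#' are half-open `[start, end)`.
#'
#' @param x events data frame or list of `hapc_event`s
#' @param path JSON output path
#' @return `path`, invisibly
#' @export
write_events_json <- function(x, path) {
  if (inherits(x, "data.frame")) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    payload <- lapply(x, function(h) {
      h <- unclass(h)
      h
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read HAPC events from JSON
#' @param path JSON path written by [write_events_json()]
#' @return list of `hapc_event`s
#' @export
read_hapcs_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(h) {
    h$channels <- as.integer(h$channels)
    structure(h, class = "hapc_event")
  })
}

#' Write phantom ground truth as JSON
#'
#' Wave specifications, per-wave event windows, per-sensor arrival times
#' and sensor positions; the full diameter field is regenerated from the
#' configuration rather than serialised.
#'
#' @param truth a `phantom_truth`
#' @param path JSON output path
#' @return `path`, invisibly
#' @export
write_ground_truth_json <- function(truth, path) {
  check_that(inherits(truth, "phantom_truth"), "write_ground_truth_json: not a phantom_truth")
  payload <- list(
    waves = lapply(truth$waves, unclass),
    event_windows = truth$event_windows,
    arrival_times_s = lapply(seq_len(nrow(truth$arrival_times_s)),
                             function(i) as.numeric(truth$arrival_times_s[i, ])),
    sensor_positions_mm = truth$sensor_positions_mm)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## Matrix CSV layout shared by diameter and residual maps: first row =
## frame times (s), first column = positions (mm), cell [1,1] empty.
write_map_matrix <- function(mat, positions, times, path) {
  out <- rbind(c(NA, times), cbind(positions, mat))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

read_map_matrix <- function(path) {
  raw <- as.matrix(utils::read.csv(path, header = FALSE))
  list(times_s = as.numeric(raw[1, -1]),
       positions_mm = as.numeric(raw[-1, 1]),
       values = unname(raw[-1, -1, drop = FALSE]))
}

#' Write a diameter profile series as CSV
#' @param diams a [diameter_profile_series()]
#' @param path CSV output path (first row = times s, first column =
#'   positions mm; invalid cells empty)
#' @return `path`, invisibly
#' @export
write_diameters_csv <- function(diams, path) {
  check_that(inherits(diams, "diameter_profile_series"),
             "write_diameters_csv: not a diameter_profile_series")
  write_map_matrix(diams$diameter_mm, diams$positions_mm, diams$times_s, path)
}

#' Read a diameter profile series from CSV
#' @param path CSV path written by [write_diameters_csv()]
#' @return a [diameter_profile_series()]
#' @export
read_diameters_csv <- function(path) {
  m <- read_map_matrix(path)
  diameter_profile_series(m$values, m$positions_mm, m$times_s)
}

#' Write a residual map as CSV
#' @param rmap a [residual_map()]
#' @param path CSV output path (same layout as [write_diameters_csv()])
#' @return `path`, invisibly
#' @export
write_residuals_csv <- function(rmap, path) {
  check_that(inherits(rmap, "residual_map"), "write_residuals_csv: not a residual_map")
  write_map_matrix(rmap$residual_mm, rmap$positions_mm, rmap$times_s, path)
}

#' Read a residual map from CSV
#'
#' Reconstructs the map values and validity; the per-position fit
#' coefficients are not stored in the CSV and come back as `NA`.
#' @param path CSV path written by [write_residuals_csv()]
#' @return a `residual_map`
#' @export
read_residuals_csv <- function(path) {
  m <- read_map_matrix(path)
  structure(list(residual_mm = m$values, positions_mm = m$positions_mm,
                 times_s = m$times_s, valid = !is.na(m$values),
                 intercept_mm = rep(NA_real_, length(m$positions_mm)),
                 slope_mm_per_s = rep(NA_real_, length(m$positions_mm))),
            class = "residual_map")
}

#' Write a polyline ROI as CSV (`x_mm`, `y_mm`)
#' @param points matrix or data frame with columns `x_mm`, `y_mm`
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_roi_csv <- function(points, path) {
  pts <- as.matrix(points)
  check_that(ncol(pts) == 2, "write_roi_csv: points must have two columns")
  utils::write.csv(data.frame(x_mm = pts[, 1], y_mm = pts[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a polyline ROI from CSV (`x_mm`, `y_mm`)
#' @param path CSV path
#' @return matrix with columns `x_mm`, `y_mm`
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path)
  for (field in c("x_mm", "y_mm"))
    if (is.null(df[[field]]))
      stop("read_roi_csv: missing column '", field, "'", call. = FALSE)
  cbind(x_mm = df$x_mm, y_mm = df$y_mm)
}

run_config_allowed <- list(
  top = c("phantom", "map", "manometry", "compare", "paths", "seed",
          "verbosity"),
  map = c("spacing_mm", "margin_mm", "min_valid"),
  manometry = c("min_amplitude_mmhg", "baseline_window_s",
                "amp_threshold_mmhg", "max_lag_s", "max_velocity_mm_s",
                "amplitude_mode"),
  compare = c("theta_high_mm", "theta_min_mm", "pad_s", "min_duration_s",
              "clock_offset_s", "imaged_segment_mm"))

#' Read and validate a pipeline run configuration
#'
#' One YAML file can drive the whole pipeline. Unknown keys, at the top
#' level or inside a module block, are rejected by name; physical
#' quantities carry units in their key names (`*_mm`, `*_s`, `*_mmhg`).
#'
#' @param path YAML config path
#' @return validated named list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), run_config_allowed$top)
  if (length(bad) > 0)
    stop("read_run_config: unknown config key '", bad[1], "'", call. = FALSE)
  for (block in c("map", "manometry", "compare")) {
    bad <- setdiff(names(cfg[[block]]), run_config_allowed[[block]])
    if (length(bad) > 0)
      stop("read_run_config: unknown key '", bad[1], "' in block '", block,
           "'", call. = FALSE)
  }
  if (!is.null(cfg$phantom)) {
    bad <- setdiff(names(cfg$phantom),
                   setdiff(names(formals(phantom_config)),
                           c("midline_points", "hapc_waves")))
    bad <- setdiff(bad, c("midline_points", "hapc_waves"))
    if (length(bad) > 0)
      stop("read_run_config: unknown key '", bad[1], "' in block 'phantom'",
           call. = FALSE)
  }
  cfg
}
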