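#' Specify one propagating contraction wave
#'
#' A wave is a Gaussian trough in luminal diameter that appears at
#' `onset_time_s`, centred at arc-length `origin_mm`, and translates at
#' constant `velocity_mm_s` (positive = antegrade, towards increasing
#' arc-length / distal). Its depth is `amplitude_fraction` of the baseline
#' diameter and its spatial half-width is `half_width_mm`. The wave is
#' extinguished once its centre has travelled `tail_length_mm`.
#'
#' @param onset_time_s onset time in seconds
#' @param origin_mm arc-length position of the trough centre at onset (mm)
#' @param velocity_mm_s propagation velocity (mm/s), non-zero
#' @param amplitude_fraction fractional occlusion in `[0, 1]`
#' @param half_width_mm Gaussian sigma of the trough in arc-length (mm)
#' @param tail_length_mm distance travelled before the wave dies (mm)
#' @return a `wave_spec` list
#' @export
wave_spec <- function(onset_time_s, origin_mm, velocity_mm_s,
                      amplitude_fraction, half_width_mm,
                      tail_length_mm = Inf) {
  check_that(is_scalar_num(velocity_mm_s) && velocity_mm_s != 0,
             "wave_spec: velocity_mm_s must be non-zero")
  check_that(is_scalar_num(half_width_mm) && half_width_mm > 0,
             "wave_spec: half_width_mm must be > 0")
  check_that(is_scalar_num(amplitude_fraction) &&
               amplitude_fraction >= 0 && amplitude_fraction <= 1,
             "wave_spec: amplitude_fraction must lie in [0, 1]")
  check_that(is_scalar_num(onset_time_s) && onset_time_s >= 0,
             "wave_spec: onset_time_s must be >= 0")
  structure(list(onset_time_s = onset_time_s, origin_mm = origin_mm,
                 velocity_mm_s = velocity_mm_s,
                 amplitude_fraction = amplitude_fraction,
                 half_width_mm = half_width_mm,
                 tail_length_mm = tail_length_mm),
            class = "wave_spec")
}

#' Default midline control points for the phantom
#'
#' A gently curved, mostly vertical midline resembling a sagittal view of
#' the descending colon, expressed in mm with the origin at the centre of
#' the first image pixel.
#' @return matrix with columns `x_mm`, `y_mm`
#' @export
default_midline_points <- function() {
  cbind(x_mm = c(90, 104, 96, 88, 100),
        y_mm = c(30, 90, 160, 230, 290))
}

#' Configure the coupled peristalsis phantom
#'
#' The defaults describe the simulated study conditions: a ~30 min
#' acquisition at 1 frame/s of a single sagittal slice, a descending-colon
#' segment of ~270 mm with 20 mm baseline lumen diameter, manometry sensors
#' every 100 mm, free breathing, and occasional low-amplitude background
#' contractions. Every stochastic element (background events, image noise,
#' pressure noise) is driven by `seed`.
#'
#' @param duration_s recording length in seconds
#' @param frame_interval_s time between frames (s); 1 s by default, with
#'   sparser sampling (e.g. 6 s) supported throughout
#' @param pixel_spacing_mm isotropic pixel size (mm)
#' @param image_shape integer `(rows, cols)` of each frame
#' @param midline_points matrix of 2-D control points in mm (`x_mm`, `y_mm`)
#' @param baseline_diameter_mm relaxed lumen diameter D0 (mm)
#' @param occlusion_floor_mm minimum achievable lumen diameter (mm)
#' @param hapc_waves list of [wave_spec()] objects
#' @param background_rate_per_min Poisson rate of low-amplitude background
#'   contractions
#' @param background_amplitude_fraction depth of background contractions as
#'   a fraction of D0
#' @param background_width_mm spatial sigma of background contractions (mm)
#' @param background_duration_s duration of one background contraction (s)
#' @param breathing_amplitude_mm peak respiratory displacement (mm),
#'   applied as a rigid vertical shift of the whole frame
#' @param breathing_period_s respiratory period (s)
#' @param noise_sd additive Gaussian image noise sd (intensity units;
#'   lumen ~ 100, background ~ 20)
#' @param sensor_positions_mm manometry sensor arc-length positions (mm),
#'   strictly increasing proximal to distal
#' @param pressure_baseline_mmhg resting intraluminal pressure (mmHg)
#' @param pressure_gain_mmhg pressure at full occlusion above baseline
#'   (mmHg)
#' @param pressure_exponent exponent of the occlusion-to-pressure coupling
#' @param pressure_noise_sd_mmhg additive pressure noise sd (mmHg)
#' @param lumen_intensity,background_intensity rendered image intensities
#' @param seed integer seed (required); keep below 2^31
#' @return a validated `phantom_config` list
#' @export
phantom_config <- function(duration_s = 1800,
                           frame_interval_s = 1,
                           pixel_spacing_mm = 2,
                           image_shape = c(160L, 96L),
                           midline_points = default_midline_points(),
                           baseline_diameter_mm = 20,
                           occlusion_floor_mm = 2,
                           hapc_waves = list(),
                           background_rate_per_min = 0.5,
                           background_amplitude_fraction = 0.15,
                           background_width_mm = 20,
                           background_duration_s = 15,
                           breathing_amplitude_mm = 3,
                           breathing_period_s = 4,
                           noise_sd = 5,
                           sensor_positions_mm = c(30, 130, 230),
                           pressure_baseline_mmhg = 10,
                           pressure_gain_mmhg = 100,
                           pressure_exponent = 1,
                           pressure_noise_sd_mmhg = 0.5,
                           lumen_intensity = 100,
                           background_intensity = 20,
                           seed) {
  check_that(!missing(seed) && is_scalar_num(seed) && seed == round(seed) &&
               abs(seed) < 2^31 - 2, "phantom_config: integer seed required")
  check_that(is_scalar_num(duration_s) && duration_s > 0,
             "phantom_config: duration_s must be > 0")
  check_that(is_scalar_num(frame_interval_s) && frame_interval_s > 0,
             "phantom_config: frame_interval_s must be > 0")
  check_that(is_scalar_num(pixel_spacing_mm) && pixel_spacing_mm > 0,
             "phantom_config: pixel_spacing_mm must be > 0")
  check_that(is_scalar_num(occlusion_floor_mm) && occlusion_floor_mm >= 0 &&
               baseline_diameter_mm > occlusion_floor_mm,
             "phantom_config: need baseline_diameter_mm > occlusion_floor_mm >= 0")
  check_that(background_amplitude_fraction >= 0 &&
               background_amplitude_fraction <= 1,
             "phantom_config: background_amplitude_fraction must lie in [0, 1]")
  for (w in hapc_waves)
    check_that(inherits(w, "wave_spec"),
               "phantom_config: hapc_waves must be a list of wave_spec objects")

  curve <- midline_curve(midline_points)
  len <- total_arc_length(curve)
  check_that(length(sensor_positions_mm) >= 1 &&
               all(diff(sensor_positions_mm) > 0),
             "phantom_config: sensor positions must be strictly increasing")
  check_that(all(sensor_positions_mm >= 0 & sensor_positions_mm <= len),
             "phantom_config: sensor positions must lie within the midline arc-length range")

  structure(list(
    duration_s = duration_s, frame_interval_s = frame_interval_s,
    pixel_spacing_mm = pixel_spacing_mm,
    image_shape = as.integer(image_shape),
    midline_points = midline_points,
    baseline_diameter_mm = baseline_diameter_mm,
    occlusion_floor_mm = occlusion_floor_mm,
    hapc_waves = hapc_waves,
    background_rate_per_min = background_rate_per_min,
    background_amplitude_fraction = background_amplitude_fraction,
    background_width_mm = background_width_mm,
    background_duration_s = background_duration_s,
    breathing_amplitude_mm = breathing_amplitude_mm,
    breathing_period_s = breathing_period_s,
    noise_sd = noise_sd,
    sensor_positions_mm = sensor_positions_mm,
    pressure_baseline_mmhg = pressure_baseline_mmhg,
    pressure_gain_mmhg = pressure_gain_mmhg,
    pressure_exponent = pressure_exponent,
    pressure_noise_sd_mmhg = pressure_noise_sd_mmhg,
    lumen_intensity = lumen_intensity,
    background_intensity = background_intensity,
    seed = as.integer(seed)), class = "phantom_config")
}

## Evaluate all RNG draws for a phantom stage under a seed derived from the
## config seed, leaving the caller's RNG state untouched.
with_phantom_rng <- function(config, stage_offset, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((config$seed + stage_offset) %% (2^31 - 1))
  force(expr)
}

## Gaussian trough factor of one translating wave on the (s, t) grid.
## Returns a matrix multiplier in [1 - A, 1]; identity before onset and
## after the wave has travelled its tail length.
wave_factor <- function(positions, times, w) {
  travelled <- w$velocity_mm_s * (times - w$onset_time_s)
  active <- times >= w$onset_time_s &
    abs(travelled) <= w$tail_length_mm
  centre <- w$origin_mm + travelled
  fac <- matrix(1, nrow = length(positions), ncol = length(times))
  if (!any(active)) return(fac)
  d2 <- outer(positions, centre[active], `-`)^2
  fac[, active] <- 1 - w$amplitude_fraction *
    exp(-d2 / (2 * w$half_width_mm^2))
  fac
}

#' Simulate the ground-truth diameter field
#'
#' Builds the luminal diameter `D(s, t)` on a regular arc-length x frame
#' grid as the baseline diameter multiplied by one Gaussian trough factor
#' per wave, clamped to `[occlusion_floor, D0]`. Low-amplitude background
#' contractions are drawn from the seeded generator (Poisson count at the
#' configured rate, uniform onset and location, raised-cosine time
#' envelope) and superposed the same way. Event windows and per-sensor
#' arrival times are computed analytically from each wave's onset, origin
#' and velocity.
#'
#' @param config a [phantom_config()]
#' @param position_spacing_mm arc-length grid step of the ground truth (mm)
#' @return a `phantom_truth` list: `diameter_mm` (positions x times matrix),
#'   `positions_mm`, `times_s`, `event_windows` (one row per wave with the
#'   interval during which the trough centre lies inside the segment and an
#'   `enters_segment` flag), `arrival_times_s` (waves x sensors matrix, NA
#'   where a sensor is never reached), `sensor_positions_mm`, and the wave
#'   list itself.
#' @export
simulate_diameter_field <- function(config, position_spacing_mm = 1) {
  check_that(inherits(config, "phantom_config"),
             "simulate_diameter_field: config must be a phantom_config")
  curve <- midline_curve(config$midline_points)
  len <- total_arc_length(curve)
  positions <- seq(0, len, by = position_spacing_mm)
  n_t <- max(1L, floor(config$duration_s / config$frame_interval_s))
  times <- (seq_len(n_t) - 1) * config$frame_interval_s
  D0 <- config$baseline_diameter_mm

  fac <- matrix(1, nrow = length(positions), ncol = length(times))
  for (w in config$hapc_waves)
    fac <- fac * wave_factor(positions, times, w)

  ## seeded background contractions: stationary troughs with a
  ## raised-cosine time envelope
  bg <- with_phantom_rng(config, 0L, {
    n_bg <- stats::rpois(1, config$background_rate_per_min *
                           config$duration_s / 60)
    if (n_bg > 0)
      data.frame(onset = stats::runif(n_bg, 0, config$duration_s),
                 centre = stats::runif(n_bg, 0, len))
    else data.frame(onset = numeric(0), centre = numeric(0))
  })
  if (nrow(bg) > 0) {
    for (i in seq_len(nrow(bg))) {
      rel <- (times - bg$onset[i]) / config$background_duration_s
      env <- ifelse(rel >= 0 & rel < 1, 0.5 * (1 - cos(2 * pi * rel)), 0)
      if (!any(env > 0)) next
      shape <- exp(-(positions - bg$centre[i])^2 /
                     (2 * config$background_width_mm^2))
      fac <- fac * (1 - config$background_amplitude_fraction *
                      outer(shape, env))
    }
  }

  D <- clamp(D0 * fac, config$occlusion_floor_mm, D0)

  windows <- wave_event_windows(config$hapc_waves, len, config$duration_s)
  arrivals <- wave_arrival_times(config$hapc_waves,
                                 config$sensor_positions_mm,
                                 config$duration_s)
  if (nrow(windows) > 0 && any(!windows$enters_segment))
    warning("simulate_diameter_field: ",
            sum(!windows$enters_segment),
            " wave(s) never enter the imaged segment", call. = FALSE)

  structure(list(diameter_mm = D, positions_mm = positions,
                 times_s = times, event_windows = windows,
                 arrival_times_s = arrivals,
                 sensor_positions_mm = config$sensor_positions_mm,
                 waves = config$hapc_waves,
                 background_events = bg),
            class = "phantom_truth")
}

## Interval [start, end) during which each wave's trough centre lies
## inside [0, segment_length], intersected with the wave's lifetime and
## the recording.
wave_event_windows <- function(waves, segment_length, duration) {
  if (length(waves) == 0)
    return(data.frame(wave = integer(0), start_s = numeric(0),
                      end_s = numeric(0), enters_segment = logical(0)))
  rows <- lapply(seq_along(waves), function(i) {
    w <- waves[[i]]
    v <- w$velocity_mm_s
    t_at <- function(s) w$onset_time_s + (s - w$origin_mm) / v
    bounds <- sort(c(t_at(0), t_at(segment_length)))
    death <- w$onset_time_s + w$tail_length_mm / abs(v)
    start <- max(bounds[1], w$onset_time_s, 0)
    end <- min(bounds[2], death, duration)
    data.frame(wave = i, start_s = start, end_s = end,
               enters_segment = end > start)
  })
  do.call(rbind, rows)
}

## Time at which each wave's trough centre passes each sensor; NA when the
## sensor is never reached during the recording or the wave's lifetime.
wave_arrival_times <- function(waves, sensors, duration) {
  out <- matrix(NA_real_, nrow = length(waves), ncol = length(sensors))
  for (i in seq_along(waves)) {
    w <- waves[[i]]
    t_arr <- w$onset_time_s + (sensors - w$origin_mm) / w$velocity_mm_s
    dist <- abs(sensors - w$origin_mm)
    ok <- t_arr >= w$onset_time_s & t_arr < duration &
      dist <= w$tail_length_mm
    out[i, ok] <- t_arr[ok]
  }
  dimnames(out) <- list(wave = seq_along(waves),
                        sensor = seq_along(sensors))
  out
}

#' Construct an image series container
#'
#' @param data numeric array `rows x cols x frames`
#' @param pixel_spacing_mm isotropic pixel size (mm)
#' @param frame_interval_s time between frames (s)
#' @return an `image_series` object
#' @export
image_series <- function(data, pixel_spacing_mm, frame_interval_s) {
  check_that(is.array(data) && length(dim(data)) == 3,
             "image_series: data must be a rows x cols x frames array")
  check_that(is_scalar_num(pixel_spacing_mm) && pixel_spacing_mm > 0,
             "image_series: pixel_spacing_mm must be > 0")
  check_that(is_scalar_num(frame_interval_s) && frame_interval_s > 0,
             "image_series: frame_interval_s must be > 0")
  structure(list(data = data, pixel_spacing_mm = pixel_spacing_mm,
                 frame_interval_s = frame_interval_s),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_series: %d x %d pixels, %d frames, %.3g mm/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_spacing_mm, x$frame_interval_s))
  invisible(x)
}

#' Render phantom image frames from a diameter field
#'
#' Each frame shows a bright lumen tube of local full width `D(s, t)`
#' centred on the midline over a dark background, with a one-pixel soft
#' edge so that the half-maximum intensity crossing sits exactly at the
#' true lumen boundary. Breathing is applied as a rigid vertical
#' sinusoidal translation of the whole frame; zero-mean Gaussian noise is
#' added last. Fails, naming the first offending frame, if the tube leaves
#' the field of view.
#'
#' @param truth a `phantom_truth` from [simulate_diameter_field()]
#' @param config the same [phantom_config()]
#' @return an [image_series()]
#' @export
render_frames <- function(truth, config) {
  check_that(inherits(truth, "phantom_truth"), "render_frames: truth must be a phantom_truth")
  p <- config$pixel_spacing_mm
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  curve <- midline_curve(config$midline_points)
  mid <- resample_polyline(curve$points, 0.5)
  D0 <- config$baseline_diameter_mm

  ## precondition: midline inside the frame with margin >= D0
  xmax <- (cols - 1) * p; ymax <- (rows - 1) * p
  check_that(all(mid[, 1] >= D0 & mid[, 1] <= xmax - D0 &
                   mid[, 2] >= D0 & mid[, 2] <= ymax - D0),
             "render_frames: midline must fit inside the image with margin >= baseline diameter")

  ## per-pixel nearest midline sample: arc-length index and distance
  px_x <- rep((seq_len(cols) - 1) * p, each = rows)
  px_y <- rep((seq_len(rows) - 1) * p, times = cols)
  arc <- cumsum(c(0, sqrt(rowSums(diff(mid)^2))))
  best_d2 <- rep(Inf, rows * cols)
  best_i <- rep(1L, rows * cols)
  for (i in seq_len(nrow(mid))) {
    d2 <- (px_x - mid[i, 1])^2 + (px_y - mid[i, 2])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  dist_px <- sqrt(best_d2)
  s_px <- arc[best_i]

  ## map pixel arc-lengths onto the truth grid
  s_idx <- clamp(round(s_px / diff(truth$positions_mm[1:2])) + 1L,
                 1L, length(truth$positions_mm))

  n_t <- length(truth$times_s)
  lum <- config$lumen_intensity; bg <- config$background_intensity
  out <- array(0, dim = c(rows, cols, n_t))
  shift_mm <- if (config$breathing_amplitude_mm > 0)
    config$breathing_amplitude_mm *
      sin(2 * pi * truth$times_s / config$breathing_period_s)
  else rep(0, n_t)

  ## FOV check: tube extent (y) plus breathing shift must stay in frame
  tube_ymin <- min(mid[, 2]) - D0 / 2 - p / 2
  tube_ymax <- max(mid[, 2]) + D0 / 2 + p / 2
  bad <- which(tube_ymin + shift_mm < 0 | tube_ymax + shift_mm > ymax)
  if (length(bad) > 0)
    stop(sprintf("render_frames: tube exits the field of view at frame %d (t = %g s)",
                 bad[1], truth$times_s[bad[1]]), call. = FALSE)

  noise <- with_phantom_rng(config, 1L, {
    if (config$noise_sd > 0)
      array(stats::rnorm(rows * cols * n_t, sd = config$noise_sd),
            dim = c(rows, cols, n_t))
    else NULL
  })

  row_idx <- seq_len(rows)
  for (t in seq_len(n_t)) {
    radius <- truth$diameter_mm[s_idx, t] / 2
    frame <- matrix(bg + (lum - bg) * clamp((radius - dist_px) / p + 0.5, 0, 1),
                    nrow = rows, ncol = cols)
    dy <- shift_mm[t] / p
    if (dy != 0) {
      ## content moves down by dy pixels: sample source row r - dy
      src <- row_idx - dy
      r0 <- clamp(floor(src), 1, rows)
      r1 <- clamp(r0 + 1, 1, rows)
      wgt <- clamp(src - r0, 0, 1)
      frame <- frame[r0, , drop = FALSE] * (1 - wgt) +
        frame[r1, , drop = FALSE] * wgt
    }
    if (!is.null(noise)) frame <- frame + noise[, , t]
    out[, , t] <- frame
  }
  image_series(out, p, config$frame_interval_s)
}

#' Simulate multi-channel manometry traces from the diameter field
#'
#' Models the water-perfused mechanism: wall contraction occludes a
#' sensor's port, raising measured pressure. Per channel at arc-length
#' `s_i`, `P_i(t) = baseline + gain * max(0, 1 - D(s_i, t)/D0)^gamma +
#' noise`. Channels are ordered proximal to distal.
#'
#' @param truth a `phantom_truth`
#' @param config the same [phantom_config()]
#' @param sampling_rate_hz sampling rate; defaults to the frame rate
#' @return a [pressure_recording()]
#' @export
simulate_manometry <- function(truth, config, sampling_rate_hz = NULL) {
  check_that(inherits(truth, "phantom_truth"), "simulate_manometry: truth must be a phantom_truth")
  sensors <- config$sensor_positions_mm
  check_that(all(sensors >= min(truth$positions_mm) &
                   sensors <= max(truth$positions_mm)),
             "simulate_manometry: sensor positions outside the arc-length range")
  if (is.null(sampling_rate_hz))
    sampling_rate_hz <- 1 / config$frame_interval_s
  t_out <- seq(0, max(truth$times_s), by = 1 / sampling_rate_hz)
  D0 <- config$baseline_diameter_mm

  s_idx <- vapply(sensors, function(s)
    which.min(abs(truth$positions_mm - s)), integer(1))
  P <- matrix(NA_real_, nrow = length(sensors), ncol = length(t_out))
  for (i in seq_along(sensors)) {
    d_t <- stats::approx(truth$times_s, truth$diameter_mm[s_idx[i], ],
                         xout = t_out, rule = 2)$y
    occl <- pmax(0, 1 - d_t / D0)
    P[i, ] <- config$pressure_baseline_mmhg +
      config$pressure_gain_mmhg * occl^config$pressure_exponent
  }
  P <- P + with_phantom_rng(config, 2L, {
    if (config$pressure_noise_sd_mmhg > 0)
      matrix(stats::rnorm(length(P), sd = config$pressure_noise_sd_mmhg),
             nrow = nrow(P))
    else 0
  })
  pressure_recording(P, sampling_rate_hz, sensors,
                     labels = paste0("ch", seq_along(sensors)))
}
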