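test_that("diameter field is the baseline when no waves are configured", {
  cfg <- quiet_config(duration_s = 60)
  truth <- simulate_diameter_field(cfg)
  expect_true(all(truth$diameter_mm == cfg$baseline_diameter_mm))
  expect_equal(nrow(truth$event_windows), 0)

  ## zero-amplitude wave is indistinguishable from no wave
  cfg0 <- quiet_config(duration_s = 60,
                       waves = list(wave_spec(10, 0, 10, 0, 30)))
  truth0 <- simulate_diameter_field(cfg0)
  expect_equal(truth0$diameter_mm, truth$diameter_mm)
})

test_that("wave trough translates at the configured velocity", {
  ## straight 400 mm midline so the trough centre reaches 300 mm in-range
  pts <- cbind(x_mm = c(60, 60), y_mm = c(30, 430))
  cfg <- quiet_config(duration_s = 120, midline_points = pts,
                      sensor_positions_mm = c(50, 150, 250),
                      waves = list(wave_spec(60, 0, 10, 0.8, 30)))
  truth <- simulate_diameter_field(cfg)
  j <- which(truth$times_s == 90)
  expect_equal(truth$positions_mm[which.min(truth$diameter_mm[, j])], 300)

  ## direct evaluation of the wave equation at a few grid points
  for (s in c(250, 300, 320)) {
    i <- which(truth$positions_mm == s)
    expected <- 20 * (1 - 0.8 * exp(-(s - 300)^2 / (2 * 30^2)))
    expect_equal(truth$diameter_mm[i, j], max(expected, 2))
  }

  ## before onset the field is at baseline
  expect_true(all(truth$diameter_mm[, truth$times_s < 60] == 20))
})

test_that("field respects the occlusion floor and baseline bounds", {
  cfg <- quiet_config(duration_s = 120,
                      waves = list(wave_spec(10, 0, 10, 1, 30)),
                      occlusion_floor_mm = 3)
  truth <- simulate_diameter_field(cfg)
  expect_true(all(truth$diameter_mm >= 3))
  expect_true(all(truth$diameter_mm <= 20))
  expect_equal(min(truth$diameter_mm), 3)
})

test_that("increasing amplitude deepens the trough and raises peak pressure", {
  mins <- c(); peaks <- c()
  for (A in c(0.2, 0.5, 0.8)) {
    cfg <- quiet_config(duration_s = 120,
                        waves = list(wave_spec(20, -60, 10, A, 30)))
    truth <- simulate_diameter_field(cfg)
    mins <- c(mins, min(truth$diameter_mm))
    peaks <- c(peaks, max(simulate_manometry(truth, cfg)$pressure_mmhg))
  }
  expect_true(all(diff(mins) < 0))
  expect_true(all(diff(peaks) > 0))
})

test_that("a wave that never enters the segment is flagged with a warning", {
  w <- wave_spec(10, -500, -10, 0.8, 30)  # moves away from the segment
  cfg <- quiet_config(duration_s = 60, waves = list(w))
  expect_warning(truth <- simulate_diameter_field(cfg),
                 "never enter")
  expect_false(truth$event_windows$enters_segment[1])
})

test_that("simulation is deterministic for identical config and seed", {
  cfg <- phantom_config(duration_s = 60, seed = 11,
                        hapc_waves = list(wave_spec(10, -60, 10, 0.8, 30)))
  a <- simulate_diameter_field(cfg)
  b <- simulate_diameter_field(cfg)
  expect_identical(a$diameter_mm, b$diameter_mm)
  expect_identical(a$background_events, b$background_events)
  expect_identical(render_frames(a, cfg)$data, render_frames(b, cfg)$data)
  expect_identical(simulate_manometry(a, cfg)$pressure_mmhg,
                   simulate_manometry(b, cfg)$pressure_mmhg)
})

test_that("static noise-free phantom renders bit-identical, time-constant frames", {
  cfg <- quiet_config(duration_s = 20)
  truth <- simulate_diameter_field(cfg)
  frames <- render_frames(truth, cfg)
  for (t in 2:dim(frames$data)[3])
    expect_identical(frames$data[, , t], frames$data[, , 1])
  pr <- simulate_manometry(truth, cfg)
  expect_true(all(pr$pressure_mmhg == cfg$pressure_baseline_mmhg))
})

test_that("rendered tube width matches the diameter field to one pixel", {
  ## straight vertical midline: the cross-section at position s is a
  ## raster row, so bright pixels can simply be counted
  pts <- cbind(x_mm = c(60, 60), y_mm = c(30, 230))
  cfg <- quiet_config(duration_s = 30, midline_points = pts,
                      sensor_positions_mm = c(30, 130),
                      waves = list(wave_spec(0, 100, 1e-6, 0.5, 30,
                                             tail_length_mm = 1e9)))
  truth <- simulate_diameter_field(cfg)
  frames <- render_frames(truth, cfg)
  p <- cfg$pixel_spacing_mm
  thr <- (cfg$lumen_intensity + cfg$background_intensity) / 2
  for (s in c(40, 100, 160)) {
    row <- round((30 + s) / p) + 1
    n_bright <- sum(frames$data[row, , 10] > thr)
    d_true <- truth$diameter_mm[which.min(abs(truth$positions_mm - s)), 10]
    expect_lte(abs(n_bright - d_true / p), 1)
  }
})

test_that("breathing shifts the whole frame by the configured amplitude", {
  ## 1 mm pixels and a 5 mm amplitude with 4 s period: at t = 1 s the
  ## shift is exactly 5 pixels, recoverable by cross-correlation; the
  ## midline runs horizontally so the vertical shift is perpendicular to
  ## the tube axis
  pts <- cbind(x_mm = c(25, 75), y_mm = c(80, 80))
  cfg <- quiet_config(duration_s = 8, midline_points = pts,
                      pixel_spacing_mm = 1, image_shape = c(160L, 96L),
                      sensor_positions_mm = c(10, 25, 40),
                      breathing_amplitude_mm = 5, breathing_period_s = 4)
  truth <- simulate_diameter_field(cfg)
  frames <- render_frames(truth, cfg)
  f0 <- frames$data[, , 1]; f1 <- frames$data[, , 2]
  shifts <- -10:10
  score <- vapply(shifts, function(k) {
    rows <- 20:140
    sum(f0[rows, ] * f1[rows + k, ])
  }, numeric(1))
  expect_equal(shifts[which.max(score)], 5)
})

test_that("rendering fails naming the first frame where the tube leaves the view", {
  cfg <- quiet_config(duration_s = 10, breathing_amplitude_mm = 40,
                      breathing_period_s = 4)
  truth <- simulate_diameter_field(cfg)
  expect_error(render_frames(truth, cfg), "frame 2")
})

test_that("pressure traces couple to the diameter field at the sensors", {
  ## antegrade wave over sensors 100 mm apart at 10 mm/s: channel peaks
  ## lag by 10 s; peak excess equals gain * amplitude for gamma = 1
  cfg <- quiet_config(duration_s = 240,
                      waves = list(wave_spec(30, -60, 10, 0.8, 30)))
  truth <- simulate_diameter_field(cfg)
  pr <- simulate_manometry(truth, cfg)
  peak_t <- apply(pr$pressure_mmhg, 1, function(x) pr$times_s[which.max(x)])
  expect_equal(diff(peak_t), c(10, 10))
  peak_amp <- apply(pr$pressure_mmhg, 1, max) - cfg$pressure_baseline_mmhg
  expect_equal(peak_amp, rep(0.8 * 100, 3), tolerance = 1e-6)

  ## coupling consistency: argmax times equal ground-truth arrivals
  expect_true(all(abs(peak_t - truth$arrival_times_s[1, ]) <=
                    1 / pr$sampling_rate_hz))
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(seed = 1, baseline_diameter_mm = 5,
                              occlusion_floor_mm = 6), "baseline_diameter")
  expect_error(phantom_config(seed = 1, sensor_positions_mm = c(100, 50)),
               "strictly increasing")
  expect_error(phantom_config(seed = 1, sensor_positions_mm = c(30, 5000)),
               "arc-length range")
  expect_error(phantom_config(duration_s = -1, seed = 1), "duration_s")
  expect_error(phantom_config(seed = 1.5), "seed")
  expect_error(wave_spec(10, 0, 0, 0.5, 30), "velocity")
  expect_error(wave_spec(10, 0, 10, 1.5, 30), "amplitude_fraction")
})
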