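# Shared fixtures: all synthetic inputs are generated in code.

## A clean phantom configuration: deterministic unless noise is asked for.
quiet_config <- function(duration_s = 240, waves = list(), seed = 7,
                         background_rate_per_min = 0, noise_sd = 0,
                         breathing_amplitude_mm = 0,
                         pressure_noise_sd_mmhg = 0, ...) {
  phantom_config(duration_s = duration_s, hapc_waves = waves,
                 background_rate_per_min = background_rate_per_min,
                 noise_sd = noise_sd,
                 breathing_amplitude_mm = breathing_amplitude_mm,
                 pressure_noise_sd_mmhg = pressure_noise_sd_mmhg,
                 seed = seed, ...)
}

## Wall corridor bracketing the config's midline at +/- offset_mm.
corridor_for <- function(config, offset_mm = 15, margin_mm = 10) {
  mid <- midline_curve(config$midline_points)
  rs <- resample_midline(mid, 2)
  wall_corridor(rs$points + offset_mm * rs$normals,
                rs$points - offset_mm * rs$normals, margin_mm = margin_mm)
}

## Run the imaging arm end to end; returns everything downstream tests need.
run_mri_arm <- function(config, spacing_mm = 2) {
  truth <- simulate_diameter_field(config)
  frames <- render_frames(truth, config)
  curve <- midline_curve(config$midline_points)
  diams <- measure_diameters(frames, curve, corridor_for(config),
                             spacing_mm = spacing_mm)
  list(truth = truth, frames = frames, diams = diams,
       rmap = residual_map(diams))
}

## True diameters on the measurement grid (positions are integer mm).
truth_on_grid <- function(truth, positions_mm) {
  idx <- vapply(positions_mm, function(s)
    which.min(abs(truth$positions_mm - s)), integer(1))
  truth$diameter_mm[idx, , drop = FALSE]
}

## Residual-map stand-in built directly from a residual matrix, for
## concordance tests that need exact trough depths.
fake_rmap <- function(r, positions_mm = seq_len(nrow(r)) * 2 - 2,
                      times_s = seq_len(ncol(r)) - 1) {
  structure(list(residual_mm = r, positions_mm = positions_mm,
                 times_s = times_s, valid = !is.na(r),
                 intercept_mm = rep(NA_real_, nrow(r)),
                 slope_mm_per_s = rep(NA_real_, nrow(r))),
            class = "residual_map")
}

## Hand-built HAPC event for concordance tests.
fake_hapc <- function(window_s, channels = 1:3, onsets_s = NULL) {
  structure(list(channels = channels,
                 onsets_s = if (is.null(onsets_s))
                   seq(window_s[1], length.out = length(channels), by = 5)
                 else onsets_s,
                 amplitudes_mmhg = rep(80, length(channels)),
                 min_amplitude_mmhg = 80,
                 window_s = window_s, velocity_mm_s = 10),
            class = "hapc_event")
}

## Multi-channel recording of Gaussian pressure pulses: `pulses` is a data
## frame with channel, peak_s, amplitude (excess over baseline), sigma_s.
pulse_recording <- function(pulses, n_channels = 3, duration_s = 600,
                            fs = 1, baseline = 10, spacing_mm = 100) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  P <- matrix(baseline, nrow = n_channels, ncol = length(t))
  for (i in seq_len(nrow(pulses))) {
    P[pulses$channel[i], ] <- P[pulses$channel[i], ] +
      pulses$amplitude[i] *
        exp(-(t - pulses$peak_s[i])^2 / (2 * pulses$sigma_s[i]^2))
  }
  pressure_recording(P, fs, spacing_mm * (seq_len(n_channels)))
}

## All permutations of a vector (row per permutation), for brute-force
## enumeration oracles.
combinat_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], combinat_perms(x[-i])))
  unname(out)
}

## Independent per-position least-squares oracle via stats::lm.
lm_residual_oracle <- function(diams) {
  r <- diams$diameter_mm * NA_real_
  for (i in seq_len(nrow(r))) {
    ok <- diams$valid[i, ]
    if (sum(ok) < 3) next
    fit <- lm(d ~ t, data = data.frame(d = diams$diameter_mm[i, ok],
                                       t = diams$times_s[ok]))
    r[i, ok] <- residuals(fit)
  }
  r
}

## Independent ridge-slope oracle: argmin position per frame, lm slope.
ridge_slope_oracle <- function(rmap, window, depth_fraction = 0.5) {
  keep <- rmap$times_s >= window[1] & rmap$times_s < window[2]
  r <- rmap$residual_mm[, keep, drop = FALSE]
  tt <- rmap$times_s[keep]
  depth <- apply(r, 2, function(col) max(-col, na.rm = TRUE))
  use <- which(depth >= depth_fraction * max(depth))
  pos <- vapply(use, function(j) rmap$positions_mm[which.min(r[, j])],
                numeric(1))
  unname(coef(lm(pos ~ tt[use]))[2])
}
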