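#!/usr/bin/env Rscript
# Step 1: simulate the coupled peristalsis phantom under the study
# conditions: ~30 min of imaging at 1 frame/s of a ~264 mm
# descending-colon segment (20 mm baseline lumen), three antegrade
# occlusive waves entering from proximal of the imaged segment, sparse
# low-amplitude background contractions, free breathing and image noise,
# with manometry sensors every 100 mm coupled to the same diameter field.
#
# Writes the frames (NIfTI), pressure traces (CSV + YAML sidecar), the
# user-drawn midline/wall ROIs (CSV) and the ground truth (JSON) under
# results/phantom/.

library(colomap)

out_dir <- "results/phantom"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

waves <- list(wave_spec(200, -80, 10, 0.8, 30),
              wave_spec(700, -80, 8, 0.8, 30),
              wave_spec(1200, -80, 12, 0.8, 30))
cfg <- phantom_config(duration_s = 1800, hapc_waves = waves, seed = 2026)

truth <- simulate_diameter_field(cfg)
frames <- render_frames(truth, cfg)
recording <- simulate_manometry(truth, cfg)

write_image_series(frames, file.path(out_dir, "frames.nii.gz"))
write_pressure_csv(recording, file.path(out_dir, "pressure.csv"))
write_ground_truth_json(truth, file.path(out_dir, "ground_truth.json"))

## the "user-drawn" ROIs: midline control points and the two wall
## delineations bracketing the lumen at baseline radius + 5 mm
write_roi_csv(cfg$midline_points, file.path(out_dir, "midline.csv"))
rs <- resample_midline(midline_curve(cfg$midline_points), 2)
off <- cfg$baseline_diameter_mm / 2 + 5
write_roi_csv(rs$points + off * rs$normals, file.path(out_dir, "wall1.csv"))
write_roi_csv(rs$points - off * rs$normals, file.path(out_dir, "wall2.csv"))

cat(sprintf("Simulated %d frames (%d x %d px, %.1f mm/px) and %d pressure channels.\n",
            dim(frames$data)[3], dim(frames$data)[1], dim(frames$data)[2],
            frames$pixel_spacing_mm, nrow(recording$pressure_mmhg)))
cat(sprintf("%d waves; %d background contractions drawn at %.2g/min.\n",
            length(waves), nrow(truth$background_events),
            cfg$background_rate_per_min))
print(truth$event_windows)
cat("Ground-truth sensor arrival times (s):\n")
print(truth$arrival_times_s)
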