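#!/usr/bin/env Rscript
# Step 4: cross-modality concordance. Aligns the residual map with the
# detected HAPCs (the phantom's two clocks coincide, so the offset is 0),
# keeps only the manometry channels inside the imaged segment, labels the
# MRI activity during each HAPC window as high / minimal / absent,
# detects MRI-only activity episodes, and writes the agreement summary
# and the overlay figure.

library(colomap)

out_dir <- "results/concordance"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rmap <- read_residuals_csv("results/mri/residuals.csv")
hapcs <- read_hapcs_json("results/manometry/hapcs.json")
recording <- read_pressure_csv("results/phantom/pressure.csv")

session <- aligned_session(
  rmap, hapcs,
  channel_positions_mm = recording$channel_positions_mm,
  imaged_segment_mm = c(0, max(rmap$positions_mm) + 1),
  clock_offset_s = 0)

classifications <- lapply(hapcs, function(h)
  classify_mri_activity(session, h, theta_high_mm = 4, theta_min_mm = 1))
episodes <- detect_mri_episodes(session)
summary <- concordance_summary(classifications, episodes)

jsonlite::write_json(
  list(classifications = classifications, episodes = episodes,
       summary = unclass(summary)),
  file.path(out_dir, "concordance.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
render_overlay_plot(session, file.path(out_dir, "overlay.png"))

print(summary)
cat(sprintf("%d MRI activity episodes, of which %d have no manometric counterpart.\n",
            nrow(episodes), sum(!episodes$overlaps_hapc)))
for (i in seq_along(classifications))
  cat(sprintf("  HAPC %d: %s (trough %.1f mm)\n", i,
              classifications[[i]]$label, classifications[[i]]$score_mm))
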