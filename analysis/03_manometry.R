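#!/usr/bin/env Rscript
# Step 3: the manometry arm. Reads the multi-channel pressure traces,
# detects contraction events against a rolling-median baseline, chains
# them into high-amplitude propagating contractions (>= 60 mmHg on >= 3
# adjacent sites, antegrade), and estimates each HAPC's propagation
# velocity.

library(colomap)

in_dir <- "results/phantom"
out_dir <- "results/manometry"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

recording <- read_pressure_csv(file.path(in_dir, "pressure.csv"))
events <- detect_contractions(recording)
hapcs <- detect_hapcs(events, recording)

write_events_json(events, file.path(out_dir, "contractions.json"))
write_events_json(hapcs, file.path(out_dir, "hapcs.json"))

cat(sprintf("%d contraction events on %d channels; %d HAPCs.\n",
            nrow(events), nrow(recording$pressure_mmhg), length(hapcs)))
for (i in seq_along(hapcs)) {
  h <- hapcs[[i]]
  cat(sprintf("  HAPC %d: channels %s, onset %.0f s, min amplitude %.0f mmHg, velocity %.1f mm/s\n",
              i, paste(h$channels, collapse = "-"), h$onsets_s[1],
              h$min_amplitude_mmhg, h$velocity_mm_s))
}
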