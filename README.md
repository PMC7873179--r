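# colomap

Simultaneous assessment of colonic motility from two modalities:
**cine-MRI** (a movie of the colonic wall, ~1 frame/s for ~30 min) and
**colonic manometry** (multi-channel intraluminal pressure). The package
is aimed at GI-motility researchers who need a tested, reproducible
implementation of the spatiotemporal motility-mapping analysis, the
manometric HAPC criteria, and a way to score agreement between the two —
together with a coupled phantom that makes the whole chain verifiable
without clinical recordings.

## What it computes

**Imaging arm.** Along a user-drawn midline of the colon segment,
perpendicular lumen diameters `d(s, t)` are measured every Δs of arc
length per frame (half-maximum edge detection inside a wall-search
corridor, sub-pixel interpolation, invalid cells masked rather than
zeroed). Each position is linearly detrended by ordinary least squares,

    r(s, t) = d(s, t) − (a_s + b_s · t),

giving the spatiotemporal **residual map**: negative residuals are
luminal narrowing (contraction). The map is rendered with time on the
x-axis and the clinical colour convention (red = contraction, yellow =
minimal activity, blue = none). A ridge regression over the trough
recovers a wave's propagation velocity.

**Manometry arm.** Per channel, contraction events are detected as
excursions above a rolling-median baseline. A **high-amplitude
propagating contraction (HAPC)** is a chain of contractions with
amplitude ≥ 60 mmHg propagating antegradely over ≥ 3 adjacent recording
sites (10 cm spacing by default); its velocity is the least-squares
slope of sensor position on onset time.

**Concordance.** HAPC windows are translated onto the MRI clock,
channels are restricted to the imaged segment, and the MRI activity
during each HAPC is labelled `high` / `minimal` / `absent` (or
`not recorded`) by residual trough depth; activity episodes with no
manometric counterpart are flagged; the summary reports counts and
integer percentages (round half up).

**Phantom.** Both modalities are simulated from one ground-truth
diameter field — translating Gaussian occlusion waves plus background
contractions, breathing and noise; pressure is a monotone function of
fractional port occlusion. Ground-truth windows and sensor arrival
times are closed-form, so both arms are scored against the same truth.

## Worked example

```r
library(colomap)
# one antegrade occlusive wave entering the imaged segment at t = 60 s
wave <- wave_spec(onset_time_s = 60, origin_mm = -60, velocity_mm_s = 10,
                  amplitude_fraction = 0.8, half_width_mm = 30)
cfg <- phantom_config(duration_s = 300, hapc_waves = list(wave), seed = 1)
truth <- simulate_diameter_field(cfg)
frames <- render_frames(truth, cfg)
rec <- simulate_manometry(truth, cfg)

# imaging arm
curve <- midline_curve(cfg$midline_points)
rs <- resample_midline(curve, 2)
walls <- wall_corridor(rs$points + 15 * rs$normals,
                       rs$points - 15 * rs$normals, margin_mm = 10)
diams <- measure_diameters(frames, curve, walls, spacing_mm = 2)
rmap <- residual_map(diams)

# manometry arm, then cross-modality agreement
hapcs <- detect_hapcs(detect_contractions(rec), rec)
ses <- aligned_session(rmap, hapcs, cfg$sensor_positions_mm,
                       imaged_segment_mm = c(0, 264), clock_offset_s = 0)
cls <- lapply(hapcs, classify_mri_activity, session = ses)
concordance_summary(cls, detect_mri_episodes(ses))
```

Output:

```
deepest residual trough: 15.8 mm below trend
ridge velocity: 9.5 mm/s
HAPCs detected: 1; velocity 10.0 mm/s; min amplitude 80 mmHg
concordance_summary: 1 HAPCs
  high          1 (100%)
  minimal       0 (0%)
  absent        0 (0%)
  not_recorded  0 (0%)
  MRI-only episodes: 1
```

The simulated 10 mm/s wave is recovered by both arms (manometry
10.0 mm/s from onset lags; imaging 9.5 mm/s from the residual ridge,
under breathing and image noise), its 0.8 occlusion couples to an
80 mmHg pressure peak, and the MRI activity during the HAPC window is
labelled `high` because the ~16 mm residual trough far exceeds the 4 mm
threshold. The one "MRI-only" episode here is the same wave seen at
positions outside the padded HAPC window.

## The analysis workflow

`analysis/` contains the numbered drivers that run the study end to end
on the default conditions (30 min at 1 frame/s, three antegrade waves,
background activity, breathing, noise), writing tables and figures
under `results/`:

```sh
Rscript analysis/01_simulate_phantom.R   # phantom: frames, traces, truth
Rscript analysis/02_motility_map.R       # imaging arm: diameters, residual map
Rscript analysis/03_manometry.R          # manometry arm: events, HAPCs
Rscript analysis/04_concordance.R        # agreement summary and overlay
```

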