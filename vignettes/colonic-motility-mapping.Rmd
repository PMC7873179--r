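---
title: "Spatiotemporal colonic motility mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal colonic motility mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Colonic manometry is the reference standard for assessing colonic
neuromuscular function: a multi-lumen catheter records intraluminal
pressure along the colon, and normal function is marked by
high-amplitude propagating contractions (HAPCs) — clusters of pressure
waves of at least 60 mmHg propagating antegradely (proximal to distal)
over at least three adjacent recording sites. Cine-MRI offers a
non-invasive alternative: a rapid single-slice acquisition (about one
frame per second for roughly 30 minutes) films the colonic wall, and
wall motion is quantified as changes in luminal diameter along the
segment. The two modalities measure different physics — pressure at
discrete ports versus geometry along a continuous midline — so their
agreement is an empirical question, and comparing them requires both
analysis chains plus a principled way to score concordance.

`colomap` implements the full comparison pipeline:

1. a **coupled phantom** that generates cine-image series and manometry
   traces from one ground-truth contraction-wave model;
2. the **imaging arm**: perpendicular diameter measurement along a
   user-drawn midline, frame-to-frame activity, and the per-position
   linearly detrended **residual map**;
3. the **manometry arm**: contraction detection and HAPC
   classification with propagation-velocity estimation;
4. the **concordance stage**: clock alignment, channel-to-segment
   restriction, per-HAPC MRI-activity labels and summary percentages.

Because no clinical recordings accompany the method, the phantom is the
primary validation instrument: both arms are scored against the same
analytically known ground truth.

## The phantom model

The luminal diameter field on the arc-length × time grid is

$$D(s, t) = \mathrm{clamp}\!\Big( D_0 \prod_k \big[ 1 - A_k\,
e^{-(s - s_{0,k} - v_k (t - t_{0,k}))^2 / 2\sigma_k^2}\,
\mathbf{1}\{t \ge t_{0,k}\} \big],\; D_{\min},\, D_0 \Big),$$

a baseline diameter $D_0$ multiplied by one translating Gaussian trough
per contraction wave and clamped to the occlusion floor $D_{\min}$. A
Gaussian trough at constant velocity was chosen because it yields
closed-form ground truth: the trough centre, the time window during
which it lies inside the imaged segment, and its arrival time at every
sensor all follow directly from $(t_0, s_0, v)$. Low-amplitude
background contractions (stationary troughs with a raised-cosine time
envelope, drawn from a seeded Poisson process) are superposed the same
way and emulate the "minimal activity" a real colon shows between
HAPCs.

Frames render the lumen as a bright tube of local full width $D(s,t)$
over a dark background. The tube edge is softened over one pixel so
that the half-maximum intensity crossing sits exactly at the true lumen
boundary — this makes the rendered images a sub-pixel-accurate oracle
for the measurement stage rather than a quantised one. Breathing is a
rigid vertical sinusoidal translation of the whole frame (the simplest
confound consistent with free-breathing acquisition), and image noise
is additive Gaussian. Rician noise would be more faithful to magnitude
MR images, but at the phantom's contrast (lumen ≈ 100, background ≈ 20,
sd ≈ 5) the two are practically indistinguishable; this is a documented
simplification.

Pressure couples to the same field through the water-perfusion
mechanism — wall contraction occludes a port and raises measured
pressure:

$$P_i(t) = P_{\text{base}} + P_{\max}\,
\max\!\big(0,\, 1 - D(s_i, t)/D_0\big)^{\gamma} + \varepsilon,$$

with $\gamma = 1$ by default. Only the qualitative mechanism is known,
so a monotone function of fractional occlusion with a configurable
exponent is the minimal committed model. With the default
$P_{\max} = 100$ mmHg, a wave of amplitude fraction $A = 0.8$ produces
an 80 mmHg peak — comfortably above the 60 mmHg HAPC criterion — while
background contractions ($A = 0.15$) stay far below it.

### Default study conditions

| parameter | default | rationale |
|---|---|---|
| duration | 1800 s | ~30 min acquisition |
| frame interval | 1 s | protocol temporal resolution; a 6 s mode is supported since sparser sampling is plausible in practice and the pipeline treats the interval as data-driven metadata |
| pixel spacing | 2 mm | single-slice FOV of several hundred mm at modest matrix size |
| segment length | ~264 mm | descending colon |
| baseline diameter $D_0$ | 20 mm | relaxed descending-colon lumen |
| occlusion floor | 2 mm | residual lumen at full contraction |
| wave velocity | 8–12 mm/s | physiological HAPC propagation speeds |
| wave amplitude fraction | 0.8 | occlusive HAPC |
| wave half-width $\sigma$ | 30 mm | HAPC pressure waves span neighbouring sites |
| sensor spacing | 100 mm | water-perfused catheter geometry (10 cm) |
| background rate | 0.5 / min | sparse low-amplitude activity |
| breathing | 3 mm at 4 s | quiet respiration |
| image noise sd | 5 | ~6 % of lumen–background contrast |

No paediatric normative distributions exist for HAPC velocity or
amplitude, so these defaults are configurable study conditions, not
normative values. The seed is a required configuration field; identical
configuration and seed reproduce frames, traces and ground truth
bit-identically.

## The imaging arm

The midline is an input, exactly as in the semi-automatic clinical
workflow: the user draws it once, together with two wall polylines. The
midline is resampled at regular arc-length spacing (default
$\Delta s = 2$ mm, chosen well below the half-width of any plausible
wave), with centred-difference tangents and normals; endpoint tangents
are one-sided, so their direction error is $O(\Delta s / 2R)$ rather
than the interior's $O(\Delta s^2)$.

The wall delineation is drawn once but the walls move every frame; the
only reading consistent with both facts is to treat the drawn polylines
as the centre of a **search corridor** (delineated wall ± a margin,
default 10 mm) within which the wall edge is located per frame.
Intensity is sampled along each perpendicular at half-pixel steps by
bilinear interpolation; on each side, the lumen extent is the distance
to the half-maximum crossing between the intensity at the midline and
the local background (mean of the outermost in-corridor samples), with
sub-pixel linear interpolation at the crossing. The diameter is the sum
of the two side extents. Cells where either side has no crossing — the
perpendicular leaves the field of view, or the midline point is not
inside the lumen — are **masked invalid, never recorded as zero**;
masks propagate through every downstream difference and fit, which
prevents measurement dropouts from masquerading as contractions.
Because the corridor margin exceeds the breathing amplitude, the rigid
respiratory shift perturbs measured diameters by less than one pixel
(this is asserted in the test suite).

Two maps derive from the diameter series $d(s,t)$:

- **activity map**: $\Delta d(s,t) = d(s,t{+}1) - d(s,t)$;
- **residual map**: per position, one ordinary least-squares line over
  the whole recording, $r(s,t) = d(s,t) - (a_s + b_s t)$, computed from
  the closed-form normal equations over valid cells. Positions with
  fewer than three valid frames are masked. A single global fit per
  position is the default (a windowed fit would be a different
  statistic); the residuals' per-position mean and covariance with time
  vanish by construction, which the tests assert to numerical
  tolerance.

Negative residuals are luminal narrowing. The rendered plot follows the
clinical convention: time in minutes on the x-axis, position on the
y-axis, red for strong contraction, yellow for minimal activity, blue
for none; colour limits sit symmetrically at a configurable quantile
(default 0.98) of $|r|$ so that a single deep event does not flatten
the rest of the map.

## The manometry arm

Water-perfused systems drift, so each channel's baseline is a centred
rolling median over 120 s — long relative to any single contraction
(a 10 mm/s wave of $\sigma = 30$ mm occupies a port for ~6 s), so the
median is uncontaminated by the events it serves to detect. Candidate
events are maximal intervals where the excess pressure exceeds half the
detection amplitude, retained when the peak excess reaches the full
amplitude (default 30 mmHg). The onset is the last upward crossing of
20 % of the peak excess before the peak — the field defines no onset
criterion; 20 % is low enough to sit on the rising edge and high enough
to be robust to baseline wander — located with linear interpolation for
sub-sample resolution.

HAPCs are built by greedy chaining in onset order: from each unused
event, extend to the next adjacent distal channel's earliest unused
event whose onset is strictly later by at most 60 s and whose implied
velocity is at most 50 mm/s (both gates generous relative to
physiological HAPC speeds; without them, unrelated events on adjacent
channels could chain). A chain is an HAPC when it spans at least three
adjacent sites and — in the default per-site mode — every participating
event reaches 60 mmHg. Whether the clinical criterion requires 60 mmHg
at every site or on average is not specified in common definitions;
the stricter per-site reading is the default and a mean-amplitude mode
is provided. Velocity is the least-squares slope of position on onset
time; equal onsets are flagged degenerate rather than returning an
infinite slope.

One timing subtlety: an event's *onset* (20 % crossing) systematically
precedes the wave's *arrival* (trough over the port) by a
waveform-dependent interval — about 5 s for the default wave shape. The
phantom's ground-truth arrival times therefore align with the traces'
pressure *peaks* (within one sample, by construction), while onsets
lead arrivals by a channel-constant interval; the recovery tests check
both properties rather than conflating the two time points.

## Concordance

The modalities run on different clocks; the offset (manometry minus
MRI) is a required input, never inferred. Only channels inside the
imaged segment (a half-open arc-length interval) participate; an empty
intersection is a hard error since no comparison is possible. For each
HAPC, the score is the deepest negative residual over the included
channels' bands (each channel ± half the inter-channel spacing) and the
HAPC window translated to the MRI clock and padded by ±15 s to absorb
alignment uncertainty. Labels: **high** at ≥ 4 mm trough depth,
**minimal** at 1–4 mm, **absent** below 1 mm. These thresholds are
calibrated on the phantom — a full-amplitude wave leaves a ~16 mm
trough, background contractions ~2–3 mm — because the clinical
high/minimal/absent call was visual and no printed thresholds exist;
they are mandatory, documented configuration, not constants.

A window lying entirely outside the MRI acquisition is labelled
**not recorded** and kept distinct from **absent** (window covered, no
signal); the summary reports both separately plus a merged count, since
a visual comparison cannot distinguish them. MRI-only episodes —
maximal intervals with trough depth ≥ 1 mm for ≥ 5 s that overlap no
HAPC window — capture activity seen by imaging but not by manometry.
Summary percentages are integers, rounded half up.

## Numerical choices and conventions

- Seconds and millimetres are the only internal units; key names carry
  units (`*_mm`, `*_s`, `*_mmhg`).
- All time and position intervals are half-open `[start, end)`.
- Image coordinates are in mm with the origin at the first pixel
  centre; arc length starts at the proximal end of the midline;
  antegrade = increasing arc length = increasing channel index,
  declared in the recording sidecar and validated at load.
- Least-squares fits use closed-form normal equations; the test suite
  checks them against `stats::lm` to 1e-9 relative tolerance.
- Degenerate inputs fail loudly (zero-length midline, tube leaving the
  field of view with the first offending frame named, non-finite
  pressure samples with channel and sample index) or are masked
  (invalid diameter cells, all-invalid positions), never imputed.

## What the phantom does and does not establish

The phantom couples both modalities to one diameter field, so it can
establish that each arm recovers what it is supposed to recover (wave
count, timing, velocity within 10 %) and that the concordance logic is
correct. The test suite exercises a full 30 min × 1 frame/s phantom
(1800 frames, 160 × 96 pixels, 132 midline positions) end to end, plus
many smaller scenarios. What the phantom cannot establish is clinical
validity: real colons move out of plane (a 2-D slice then mimics
contraction), real walls have texture and neighbouring structures, real
catheters record events the imaging plane never sees, and real
breathing is not rigid translation. Passing tests therefore validate
the computational pipeline, not the modality agreement itself — which
is precisely the empirical question the pipeline exists to study.

## Known limitations

- No 3-D geometry or out-of-plane motion; no transit of bowel content.
- No automatic midline/wall segmentation — the ROIs are inputs by
  design.
- Gaussian (not Rician) image noise.
- The low-amplitude motor-pattern taxonomy (cyclic and retrograde
  patterns) is out of scope; water-perfused catheters at 10 cm spacing
  are unreliable for it.
- No statistical agreement coefficients: with a handful of events per
  session, raw counts and percentages are the honest summary.
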