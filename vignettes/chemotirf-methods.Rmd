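---
title: "Methods: quantifying chemotactic invasion and polarised endocytosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chemotactic invasion and polarised endocytosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chemotirf quantifies two layers of a chemotactic-invasion experiment: the
cell-scale migration readout of the agarose-spot assay (cells invading
under a chemoattractant-loaded agarose drop, followed by overnight
timelapse) and the membrane-scale TIRF readout (clathrin/EGFR puncta,
caveolin, focal adhesions in the adherent plasma membrane of migrating
cells). Because no public image data accompany these assays, the package
ships a synthetic-data generator that plants known ground truth; every
analysis stage is validated by recovering what was planted. This vignette
explains the models, the tunable parameters, and the design decisions
taken where the procedures leave latitude.

## The synthetic migration field

**Model.** Each cell is a biased-persistent random walk sampled every 10
minutes over a 14 h window. The heading at step $t$ is

$$h_t = \mathrm{rot}_{\varepsilon_t}\!\left(\widehat{p\,h_{t-1} + (1-p)\,u}\right),
\qquad \varepsilon_t \sim \mathcal{N}(0, \sigma^2),$$

where $u$ is the unit target direction, $p$ the persistence weight
(default 0.7) and $\sigma$ the per-step heading noise. Step lengths are
lognormal about the nominal speed (baseline 0.8 µm/min, log-SD 0.3).
This is the simplest walk with independently tunable directional bias and
angular spread; it does not attempt to model substrate mechanics,
cell–cell interaction, or speed–persistence coupling.

**Migration probability.** Each cell is independently a "migrator" with
the preset's probability: migrators head toward the spot interior
(perpendicular to the spot edge) and cross into the spot within the
window; non-migrators walk persistently about a random outward direction
and stay outside. Cells are always seeded 80–200 µm outside the edge, so
"migrated" (final position inside *and* edge crossed during the track) is
unambiguous. The migrated fraction is therefore a consistent estimator of
the preset probability, with binomial error.

**Treatment presets** are frozen constants, not tunables. Control (and
the non-silencing and caveolin1-knock-down conditions, which the assay
finds indistinguishable from control) uses migration probability 0.5 —
a typical fraction for a responsive population over an overnight assay —
and speed scale 1. Dynamin inhibition multiplies the migration
probability by 0.4 and the speed by 0.5; AP2 (α-adaptin) knock-down
multiplies the migration probability by 0.35. These ratios are exactly
the effect sizes the assay reports, so downstream acceptance checks are
parameter recovery, not curve fitting. One consequence of encoding the
motility effect as a single speed multiplier: among still-migrating
cells, total path length, net displacement and average velocity all
decrease by the same ~50% in expectation (velocity is path over a fixed
elapsed time, so the three cannot be set independently); the reported
per-metric decreases of 45–50% all lie within the recovery tolerance of
this single-knob design.

**Angular calibration.** The one free parameter of the walk, the
per-step heading-noise SD, is fixed at 9.72° by a one-time Monte-Carlo
calibration so that control migrating tracks deviate from the
perpendicular by 2.80° on average (unsigned origin-to-endpoint angle).
At this calibration the dispersion of the unsigned angle is ≈2.1°,
consistent with the ±2.3° the assay reports for the same quantity. The
calibration is packaged as a constant; `field_config()` exposes it for
sensitivity analyses but the default is the calibrated value.

## The synthetic TIRF field

One elliptical adherent cell (default semi-axes 8.5 × 5.5 µm at
0.1 µm/px) is rendered with its front along +x. Diffraction-limited
puncta are isotropic Gaussians (σ = 1.5 px, a typical TIRF point-spread
scale), amplitude = SNR × noise SD (defaults 10 × 10 grey values) on a
constant background (100), with additive Gaussian read noise. A full
Poisson-Gaussian camera model was considered and rejected: at the
photon counts typical of these movies the Gaussian approximation is
adequate, and a single noise knob keeps the planted SNR exact.

Punctum fates are planted: *static* spots jitter by 0.05 px, *lateral*
spots drift linearly by a net 0.8–1.6 µm over the video (above the
0.5 µm lateral threshold), *disappearing* spots drop to background
within two frames at a planted event frame — so the "rapid" criterion is
satisfiable by construction — and optionally a fraction of disappearing
spots reappear in place after 5 frames (planted negatives for the event
caller). Planted spots keep a minimum separation of 3σ + 1 px;
closer pairs are unresolvable at the diffraction limit and would be one
spot in any real field. Global photobleaching multiplies whole frames by
$(1-\beta)^{t-1}$. Positions of disappearing spots are drawn by polarity
region with configurable relative rates (`front_bias`), which is how a
front-polarised endocytic field is emulated.

The second channel, when enabled, renders partners co-positioned (within
0.5 px per axis) with an exact-count subset of channel-1 puncta —
`round(fraction × n)` per cell rather than Bernoulli draws, a stratified
planting that removes needless between-cell variance while trivially
matching the configured fraction — plus independent sparse distractors
(default 5 per cell, giving a ~1% analytic chance of a random hit at the
3 px colocalisation radius, mirroring the near-zero shifted-region
controls these experiments show).

Focal adhesions are rendered as smoothed ellipse plateaus (default
2 × 0.5 µm) with planted disassembly profiles: constant until a planted
onset frame, linear decline to zero at a planted end frame. For
chance-overlap nulls the generator plants an independent punctum channel
as a spatial Poisson process whose density is computed analytically from
the discrete dilated-ellipse area so that the probability of at least
one punctum inside a dilated adhesion mask equals the configured value
(default 0.07).

## Migration metrics

Definitions follow the tracking conventions of the assay software:
path length is the sum of Euclidean steps; distance from origin is the
start-to-end displacement; the elliptical factor is width/length ∈ (0, 1]
(width and length are swapped with a warning if given in the wrong
order). *Average velocity* is ambiguous in the field — path per time or
displacement per time — and the package defaults to path per elapsed
time, consistent with reporting total path length alongside; the
displacement-based variant is available via `mode = "displacement"`.
The migration angle is the unsigned angle between the origin-to-endpoint
vector and the spot perpendicular, reported in [0°, 180°].

## The polarity partition

The migration axis is the perpendicular to the spot edge — justified by
the angular calibration above, which shows tracks deviate from it by
under 3° on average — rather than each cell's own displacement. The cell
mask's projected extent along this axis is split into **three equal
lengths**; the front band is nearest the spot interior. Equal length,
not equal area: the area normalisation applied to all per-region counts
is only meaningful because band areas differ. Two conventions are fixed
and tested: points exactly on a band boundary are assigned frontward,
and band extent comes from the mask's own projection (a bounding-box
variant is available by flag; the two differ only for oblique axes).
Disconnected masks are reduced to their largest component with a
warning.

## Punctum detection, linking, and the event criteria

Detection is Laplacian-of-Gaussian blob detection (zero-mean inverted
LoG kernel at the punctum scale), thresholded at 5 robust (MAD) noise
SDs of the response — under one false positive per frame on pure noise —
with sub-pixel refinement by the response-weighted centroid of a 5×5
window (~0.15 px median error at SNR 10). Linking is greedy
nearest-neighbour within 2 px per step, bridging gaps up to 2 frames,
with ties broken by distance then track id. The original analyses were
manual; these are the standard algorithmic stand-ins, fully
parameterised.

Fates: *lateral* if net displacement ≥ 0.5 µm; otherwise *static* if the
track survives to the final frame; *disappearing* if it ends early with
the intensity at its terminal position at background (within 2 noise
SDs, checked over the two frames after the end so the half-intensity
transition frame cannot mask the drop); *censored* if it ends early
without a clean drop (e.g. a detection dropout).

A disappearance is accepted as an endocytic event only when all three
criteria hold:

1. **Rapid** — the intensity falls from its pre-event plateau (last
   frame at ≥90% of the plateau) to ≤ background + 2 noise SDs within 10
   frames, counted inclusively from the last bright frame. The plateau
   is the median of the upper half of the pre-event trace, so a decline
   already under way cannot drag the plateau (and the last-bright frame)
   downward and disguise a slow fade as rapid.
2. **No reappearance** — no detection within 3 px of the terminal
   position during the 10 frames after the track ends. Tracks ending
   within 10 frames of the end of the stack are censored, not called.
3. **Not photobleaching** — no quantitative criterion exists in the
   field for this exclusion, so it is operationalised as stability of
   the cell-wide mean intensity: the event is vetoed when the mean
   declines by ≥10% (flag-tunable) over the event window. Global
   bleaching depresses the whole field, so this cleanly separates
   fade-of-everything from disappearance-of-one-spot.

Event calling is monotone in the bleaching tolerance by construction
(relaxing it can only add events), a property the test suite checks.

## Colocalisation procedures

The object-based procedure mirrors manual circling: 50 channel-A puncta
are sampled without replacement; a query colocalises when any channel-B
centroid lies within 3 px (the circled-region radius). The chance
control displaces the same 50 regions "slightly": the displacement
magnitude is drawn from 2–4 query radii — close enough to preserve local
density, far enough that the new region contains no channel-A punctum
(enforced, with bounded retries; failures are skipped and counted).
Both the query sample and the shifts are seeded. Note that the observed
fraction estimates the planted colocalisation *plus* the analytic chance
term (distractor density × circled area, ~1% at the defaults); the
shifted control estimates exactly that chance term, which is how the
procedure separates signal from coincidence.

The pixel-shift profile slides one channel past the other one pixel at a
time along an axis and reports the Pearson coefficient of the overlap at
each shift; colocalised structure produces a peak at zero decaying over
a few pixels, while structure without colocalisation gives a flat
profile. The zero-shift value equals the standard Pearson coefficient
exactly; constant overlaps yield missing values rather than errors.
Kymographs sample each channel along a fixed line by bilinear
interpolation at one sample per pixel-size step, so a 10 µm line at
0.1 µm/px yields exactly 100 positions.

## Focal-adhesion kinetics

Segmentation thresholds at background + max(4 noise SDs, half the
99.9th-percentile amplitude). The half-amplitude component places the
contour of a plateau-like object at its true outline (FWHM criterion);
the noise floor keeps blank frames empty; the 0.25–15 µm² size filter
removes speckle and merged sheets. Shape comes from intensity-weighted
second moments (fitted ellipse). Adhesions in these assays are
positionally stable over a disassembly window, so per-frame intensity is
integrated within the reference-frame mask of each object.

Disassembly timing uses two thresholds the source procedures leave
unstated, fixed here and logged in every output: onset = last frame at
≥90% of the plateau, end = first later frame at ≤ background + 2 noise
SDs (floored at 5% of the plateau); the time is (end − onset) × frame
interval. The measurement is invariant to rescaling the trace. With a
linear planted ramp these thresholds span ~85% of the planted ramp
duration — the measured time is the 90%-to-background crossing, which is
the quantity the definition names, not the full ramp; the tests assert
recovery against that analytic expectation. Censored traces (never
declining to background) return nothing rather than a guess.

Group comparisons default to the Mann–Whitney U test — no test is named
in the source procedures, and rank tests are robust to the skewed time
distributions these assays produce — with a Welch t-test by flag.
Multi-condition reports show raw p-values with a clearly-labelled
Holm-adjusted column; comparisons are treated-vs-control only.

## Numerical conventions and problem sizes

Pixel coordinates are 1-based with x = column, y = row and pixel centres
at integer coordinates; physical positions are (px − 1) × pixel size.
All randomness flows from one seed; nested stages draw 32-bit sub-seeds
from the master stream, so identical configurations reproduce identical
outputs bit for bit. The packaged test and acceptance runs use problem
sizes chosen to make the planted effects statistically decisive at
interactive run times: 36 fields × 25 cells per condition for the
dynamin contrasts, 22 fields for the knock-down contrasts, 14
two-channel cells × 50 circled clusters for colocalisation, 30 cells ×
12 adhesions for the overlap null, 100 tracks for the angle calibration
and ~300 linked tracks for the event-caller characterisation.

## What passing tests do and do not show

The generator plants Gaussian spots, ellipse adhesions, a constant
background and a rigid elliptical cell. Real TIRF fields have structured
background, evanescent-depth intensity variation, cell-shape change,
focus drift, and detection-limited punctum densities. Recovery of
planted truth therefore validates the *computations* — metric formulas,
partition geometry, criteria logic, estimator calibration — not the
detector's robustness to real-world imaging artefacts. Parameters most
likely to need retuning on real data are the detection threshold
(`k_sigma`), the linking step, the lateral threshold, and the
photobleaching tolerance; all are exposed as arguments.
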