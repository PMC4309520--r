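# chemotirf

Quantification of chemotactic invasion and polarised endocytosis from
TIRF microscopy.

## What this is for

In the agarose-spot assay, cells invade beneath a chemoattractant-loaded
agarose drop (e.g. EGF for breast- and pancreatic-cancer lines) and are
followed by overnight timelapse; TIRF microscopy of the same migrating
cells resolves clathrin-coated pits, chemoattractant-receptor clusters,
caveolae and focal adhesions in the adherent plasma membrane.
`chemotirf` implements the full quantification stack for such
experiments:

- **Migration metrics** — migrated-cell counts (final position inside
  the spot *and* edge crossed), total path length
  $L = \sum_i \lVert x_{i+1} - x_i \rVert$, distance from origin
  $\lVert x_n - x_1 \rVert$, average velocity $L/T$, elliptical factor
  (width/length ∈ (0, 1]), unsigned migration angle to the spot
  perpendicular, percent change between conditions, and wound-healing
  distance.
- **Polarity partition** — the cell mask split into front/middle/back
  bands of equal length along the axis perpendicular to the spot edge,
  with per-area normalisation of all regional counts.
- **Punctum analysis** — Laplacian-of-Gaussian detection, greedy
  nearest-neighbour linking, fate classification
  (static / lateral / disappearing / censored), and endocytic
  disappearance-event calling under three criteria: the drop is rapid
  (within 10 frames), the spot does not reappear within 10 frames, and
  the drop is not attributable to global photobleaching.
- **Colocalisation** — the 50-circled-cluster object procedure with a
  shifted-region chance control, the pixel-shift Pearson correlation
  profile, and kymographs.
- **Focal adhesions** — segmentation, per-region counts, disassembly
  times from intensity traces (90%-plateau onset to background
  crossing), punctum–adhesion overlap fractions, and group comparisons
  (Mann–Whitney U by default).
- **Synthetic data** — a generator that plants known ground truth
  (tracks, punctum fates, colocalisation labels, adhesion lifetimes)
  under frozen treatment presets (`control`, `dynasore`, `nsc_sirna`,
  `alpha_adaptin_sirna`, `cav1_sirna`), so every stage above is
  verifiable without microscope data.

## Worked example

Simulate a control vs dynamin-inhibition experiment (12 fields of view
per condition) and report the migration contrasts:

```r
library(chemotirf)

rc  <- run_config(presets = c("control", "dynasore"), n_fields = 12,
                  seed = 42)
rep <- run_experiment(rc)
print(rep)
#> summary_report
#> mean migrated cells per field:
#>  condition n_migrated
#>    control  12.166667
#>   dynasore   3.666667
#>
#> comparison vs control:
#>  condition            metric control_mean treated_mean pct_decrease  p_value
#>   dynasore        n_migrated       12.167        3.667        69.86 2.95e-05
#>   dynasore           path_um      675.468      336.241        50.22 9.83e-24
#>   dynasore       distance_um      657.720      327.976        50.13 9.83e-24
#>   dynasore     velocity_um_h       48.248       24.017        50.22 9.83e-24
#>   dynasore elliptical_factor        0.454        0.449         1.07 7.18e-01
```

The dynamin-inhibition preset plants a 60% drop in migrated cells and a
50% speed reduction; at 12 fields the measured count decrease (69.9%)
still carries binomial noise, while the per-track motility metrics
recover the planted 50% tightly. The elliptical factor shows no planted
effect and correctly reports none.

Render a TIRF timelapse, call endocytic disappearance events, and check
them against the planted truth:

```r
cfg <- tirf_config(n_puncta = 60, n_frames = 30)
tg  <- make_tirf_timelapse(cfg, seed = 42)
det   <- detect_puncta_stack(tg$stack, "puncta")
trk   <- link_puncta(det)
fates <- classify_fates(trk, tg$stack, "puncta")
table(fates$fate)
#>     censored disappearing      lateral       static
#>            3           12           18           30
ev <- call_disappearance_all(trk, tg$stack, channel = "puncta",
                             mask = tg$mask)
nrow(ev)                                  # 12 events called
sum(tg$puncta$fate == "disappearing")     # 13 planted
```

A thin command-line front end over the same functions is installed at
`inst/cli/chemotirf.R` (subcommands `simulate-field`, `simulate-tirf`,
`metrics`, `report`).

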