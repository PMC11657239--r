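# gaitdtw

Quantitative walkability assessment from a single wearable IMU.

Sidewalk pavement materials differ in stiffness and rebound, and those
properties shape gait stability and the rate at which walking fatigue
accumulates — most strongly in older pedestrians. `gaitdtw` turns raw
tri-axial accelerometer and gyroscope recordings from a lumbar-mounted
inertial measurement unit (IMU) into per-gait-cycle instability scores and
cohort-level comparisons across flooring materials (wood, asphalt,
concrete block, cement), walking distance (200 m sections of a 1,200 m
walk) and age group (20–30 through 60+). It is aimed at researchers in
wearable-sensor gait analysis, urban-planning instrumentation and digital
public health.

## Method at a glance

1. **SVM** — each tri-axial sample collapses to the signal vector
   magnitude `√(ax² + ay² + az²)`, an orientation-robust scalar.
2. **Filter + normalize** — zero-phase Butterworth low-pass (6 Hz
   default), then per-recording z-scoring.
3. **Segmentation** — gait cycles are successive prominent SVM peaks
   (prominence ≥ 0.5 SD, ≥ 0.4 s apart), binned by cumulative distance.
4. **DTW scoring** — each cycle's dissimilarity to its (material, age
   group) stratum's reference cycle is the minimal accumulated local cost

   `D(i,j) = |aᵢ − bⱼ| + min{D(i−1,j), D(i,j−1), D(i−1,j−1)}`

   over all monotone, continuous, boundary-respecting warping paths. The
   reference ("typical") cycle is the DTW medoid of its stratum.
5. **Aggregation + statistics** — cell statistics per material × age
   group × distance bin, participant-level means, percent-change trends,
   one-way ANOVA across materials and Tukey boxplot summaries.

A seeded synthetic gait simulator reproduces the full study design
(80 participants × 4 materials × 1,200 m) with known ground truth, so the
entire pipeline is testable without hardware. See the methods vignette
(`vignettes/walkability-dtw.Rmd`) for the model, parameter defaults and
design rationale.

## Worked example

```r
library(gaitdtw)

cfg <- default_pipeline_config()
cfg$seed <- 1L
cfg$simulate$n_per_group <- 2L      # 10 participants, 40 recordings
cfg$simulate$sample_rate_hz <- 25
cfg$scoring$cycle_step <- 6L
cfg$output_dir <- tempfile("gaitdtw-")

res <- run_pipeline(cfg)
#> [gaitdtw] recordings in: 40
#> [gaitdtw] cycles detected: 36256, dropped: 0, scored: 6057
#> [gaitdtw] cells reported: 120

sort(tapply(res$scores$dtw, res$scores$material, mean), decreasing = TRUE)
#>         cement        asphalt concrete_block           wood
#>       5.119273       3.137782       2.748304       2.156823

res$percent_change
#>         material first_bin_mean last_bin_mean percent_change
#> 1        asphalt       2.718625      3.528251       29.78070
#> 2         cement       4.709124      5.309752       12.75455
#> 3 concrete_block       2.372991      3.148072       32.66261
#> 4           wood       1.867046      2.549677       36.56211
```

Cement walks score the highest mean DTW (least stable gait) and wood the
lowest, and every material's mean score rises from the first to the last
200 m section — the fatigue trend. Scores are on the normalized-signal
scale: only orderings and relative changes are meaningful, not absolute
magnitudes.

The worked-arithmetic helpers operate directly on published summary
numbers:

```r
round(percent_change(28.9, 35.2), 1)                 # 21.8  (% rise, 200 m -> 1,200 m)
round(anova_from_ss(8524.6, 3, 5043.2, 76)$f_ratio, 1)  # 42.8
```

A thin CLI wrapper is included at `inst/scripts/gaitdtw` (subcommands
`simulate` and `run`, YAML config, deterministic outputs carrying a
config hash and seed).

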