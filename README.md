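# fretkin

Quantification of ATP dynamics from two-channel (donor, FRET) fluorescence
time-lapses of genetically encoded FRET biosensors, built around the
workflow used to map spatial patterns of ATP depletion in the *Drosophila*
wing-disc pouch: sensitized-emission FRET efficiency imaging, an
organizer / non-organizer region scheme, and constrained
four-parameter-logistic decay kinetics. A ground-truth-annotated synthetic
scene generator inverts the analysis formulas, so every stage is
validated by round trip and parameter recovery.

## The model

With donor image `I_D` and FRET-channel image `I_F` (both smoothed with a
5 × 5 averaging kernel and background-subtracted), and a bleedthrough
fraction `β = I_bth / I_D` measured on a donor-only specimen:

    I_FRET = I_F − β·I_D
    η      = I_FRET / (I_D + I_FRET)

Mean η traces of named regions (20-µm circular ROIs on the AP/DV
compartment boundaries and outside them, or freehand compartments) are
fitted, post drug addition, with the constrained four-parameter logistic

    f(t) = base + (max − base) / (1 + (t½ / t)^n)

with `base` fixed at 0.2827 (the sensor floor: Gaussian mean − 2 SD of an
ATP-insensitive sensor variant), `max ≤ 0.7`, and the two reported
parameters: half-life `t½` (min) and Hill coefficient `n` (negative for a
decline; more negative = steeper).

## Worked example

Simulate a two-region virtual disc (organizer half-life 45 min,
non-organizer 30 min, Hill −2.3), run the full pipeline on a 26-disc
cohort, and compare the fitted half-lives:

```r
library(fretkin)

bench <- default_two_region_scene()
res <- run_pipeline(list(
  scene = bench$scene, kinetics = bench$kinetics, geometry = bench$geometry,
  n_discs = 26L, seed = 2024L, out_dir = "results/cohort",
  comparison = list(regions = c("ORG", "NO"), param = "t_half",
                    test = "kruskal")))
```

Running `analysis/03_fit_cohort.R`, which wraps exactly this, prints:

```
26-disc cohort (true half-lives: ORG 45, NO 30 min; hill -2.3)
  median per-disc t_half: ORG 44.5 min, NO 29.9 min
  median per-disc hill:   ORG -2.31, NO -2.31
  mean-trace fits: ORG t_half 44.5 min, NO 29.9 min
  Kruskal-Wallis on t_half: H = 38.26, p = 6.18e-10 (n = 26 discs)
```

i.e. the pipeline recovers both generating half-lives within ~1% from
rendered, noisy, bleedthrough-contaminated image stacks, and the
organizer / non-organizer contrast is detected as highly significant,
while the matching equal-kinetics null (`analysis/04_null_calibration.R`)
stays non-significant in 97 of 100 seeded runs.

The numbered scripts under `analysis/` run the stages individually:
`01_simulate_scene.R` (render one disc + calibration pair to TIFF),
`02_efficiency_traces.R` (bleedthrough estimate, per-pixel η, ROI traces
from file), `03_fit_cohort.R`, `04_null_calibration.R`, and
`05_recover_published_kinetics.R` (noiseless recovery at the published
regional parameter sets). All outputs land under `results/`.

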