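---
title: "Quantifying ATP dynamics from FRET biosensor time-lapses"
author: "fretkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ATP dynamics from FRET biosensor time-lapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkin)
```

## The measurement

Genetically encoded ATP sensors of the ATeam family report cytosolic ATP as
a change in Förster resonance energy transfer (FRET) between a CFP-type
donor and a cpVenus acceptor. Under donor excitation two channels are
recorded: the donor emission $I_D$ and the sensitized acceptor emission
$I_F$. Part of the donor emission leaks into the acceptor detection band;
this *bleedthrough* fraction $\beta$ is measured once, on a specimen
carrying only the donor fluorophore, as

$$\beta = \frac{I_{bth}}{I_D},$$

and `estimate_bleedthrough()` computes it as the ratio of
background-subtracted masked means. The ratio-of-means aggregation is used
rather than the mean of per-pixel ratios because near-zero donor pixels
make the latter unstable; on noiseless data the two agree.

Per frame, `compute_efficiency()` applies the fixed order *smooth →
background-subtract → bleedthrough-correct → ratio*:

$$I_{FRET} = I_F - \beta I_D, \qquad
  \eta = \frac{I_{FRET}}{I_D + I_{FRET}},$$

after smoothing both channels with a square averaging kernel (default
$5 \times 5$, edge pixels replicated). $\eta$ is a monotone readout of ATP
binding; it is unitless and, for physical signals, lies in $[0, 1]$.

Numerical policy: pixels whose corrected total $I_D + I_{FRET}$ falls below
`min_denominator` (default 1 ADU) are flagged invalid rather than divided;
efficiencies outside $[0,1]$ by more than $10^{-9}$ are flagged invalid,
while excursions within $10^{-9}$ (floating error) are clipped. Invalid
pixels are carried as `NA` and excluded from region means — never silently
zeroed, so validity counts always partition the pixel grid. How an
out-of-range pixel should be treated is genuinely open (clip, discard, or
flag); flagging was chosen because it is lossless and auditable
downstream.

## Regions of the wing-disc pouch

The spatial question is whether the *organizer* stripes of the pouch — the
dorsal–ventral (DV) boundary and the stripe just anterior of the
anterior–posterior (AP) boundary, where morphogen signaling is high —
deplete ATP more slowly than the rest of the tissue when ATP production is
inhibited.

`make_roi_scheme()` encodes the nine-ROI scheme: circular ROIs of 20 µm
diameter, three along each boundary with the central circle shared (five
distinct organizer circles), plus four non-organizer circles at the
quadrant midpoints. Composite regions are aggregated as the *unweighted
mean of the constituent ROI means* (the ROIs are "averaged together"), not
by pooling pixels; `extract_trace()` implements both and the tests assert
which one composite regions use. Whether the original aggregation weighted
ROIs by valid-pixel count is unknowable from the publication; unweighted
was chosen and is documented here. Compartments (dorsal/ventral and their
anterior/posterior splits) are instead single polygon regions with
pixel-pooled means, matching how a freehand selection is measured.

Two placement parameters are not stated in the source material and are
exposed as arguments: the ROI spacing along the boundaries (default
$1.5\times$ diameter, which keeps the circles disjoint) and the
non-organizer positions (default: midway between the boundary intersection
and the pouch bounding-box corners). Circle rasterization includes a pixel
when its centre lies within the radius, inclusive — reproducible and
orientation-independent. Landmarks come from a JSON sidecar rather than
interactive clicking so that region definitions are scriptable and
testable.

## Decay kinetics

Post-drug region traces are fitted with a constrained four-parameter
logistic,

$$f(t) = \mathrm{base} + \frac{\mathrm{max} - \mathrm{base}}
  {1 + (t_{1/2}/t)^{n}},$$

with the two parameters of interest being the half-life $t_{1/2}$ (minutes;
time at which $f = (\mathrm{base}+\mathrm{max})/2$, an identity that holds
for any $n$ and is asserted to $10^{-12}$ on every fit) and the Hill
coefficient $n$ (unitless; the curve decreases, so $n < 0$, and a more
negative $n$ is a steeper transition at $t_{1/2}$).

* `base` is fixed at **0.2827**, the sensor floor: the Gaussian mean minus
  twice the SD of the efficiency distribution of an ATP-insensitive sensor
  variant. `calibrate_floor()` recomputes this from a sample of
  efficiencies, by moments or by a least-squares Gaussian fit to the
  density histogram; on Gaussian data the two agree within 1%.
* `max` is fitted but bounded above by **0.7**, the highest reliably
  recorded mean efficiency.
* Time is re-expressed as minutes since drug addition. Whether the
  original fits used time-since-drug or time-since-acquisition is not
  stated; since-drug was chosen because the drug arrows in the kinetic
  plots mark that origin, and the $t = 0$ singularity of the curve is
  avoided by construction because the first post-drug frame sits at
  $t =$ one frame interval.

`fit_decay()` uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, cost tolerance $10^{-10}$) with deterministic
starting values: the plateau from the first five post-drug points, the
half-life from the first crossing of the half level (else half the
duration), and Hill $\mp 2$ with the sign chosen from the trace direction;
a fixed restart grid on the Hill start (magnitudes 1, 2, 5) runs only if
the first attempt fails, so there is no randomness in the fit. Bounds:
$\mathrm{base} < \mathrm{max} \le 0.7$, $t_{1/2} \in (0,\, 10 \times
\mathrm{duration}]$, $n \in [-50, 50]$. Missing frames are dropped from
the residual, not interpolated. A fit is reported `converged = FALSE` when
the solver fails or a parameter lands on a bound (a constant trace ends up
there); a half-life beyond the observation window is flagged because it is
then weakly identified; a positive fitted Hill (rising trace) is flagged
too. `fit_cohort()` fits every disc × region and, separately, each
region's mean trace (unweighted mean over discs per timepoint); published
half-lives could come from either summary, so both are emitted.

## The synthetic scene generator

Real calibration data for this pipeline are raw microscopy stacks that are
not machine-readable here, so validation uses a generator that *inverts*
the analysis formulas on a virtual pouch. Given a per-pixel true
efficiency $\eta$ and total corrected intensity $T$:

$$I_D = (1-\eta)\,T,\quad I_{FRET} = \eta\,T,\quad
  I_D^{raw} = bg_D + I_D + \varepsilon,\quad
  I_F^{raw} = bg_F + I_{FRET} + \beta I_D + \varepsilon,$$

with $\varepsilon$ iid Gaussian per channel and pixel. With zero noise the
identity $(I_F^{raw}-bg_F) - \beta(I_D^{raw}-bg_D) + (I_D^{raw}-bg_D) = T$
holds exactly at every pixel, and running the efficiency pipeline on a
rendered stack reproduces the true $\eta$ map to better than $10^{-9}$ —
the round-trip property the test suite and the analysis scripts lean on.

Design choices, and what they do *not* model:

* Geometry is a rectangle with axis-aligned 20-µm stripes whose
  intersection is the organizer; real pouches are curved. Geometry only
  enters through region membership, never through a formula, so this does
  not limit what the round-trip tests show about the arithmetic — but it
  does mean the tests say nothing about how well hand-placed landmarks
  track a curved boundary.
* Noise is additive Gaussian per channel, not Poisson; EMCCD data at these
  intensities are well approximated and the analysis itself is
  noise-model-agnostic. The noise model is a named field so a shot-noise
  variant can be added without changing the contract. No optical PSF,
  photobleaching, z-structure or tissue movement is simulated; the
  smoothing step is therefore exercised only for its numerics, not for its
  effect on real optics.
* Pre-drug frames sit on the plateau $\eta = \mathrm{max}$ (drugs are
  added at the 0- or 10-minute timepoint and fits start at drug addition;
  control discs are stable over the 2-h window).
* Default acquisition: 130 frames at 1 frame/min, drug at 10 min. The
  1-min interval is inferred from the "1–10 min" and "121–130 min"
  averaging brackets used for the before/after comparisons; it is the only
  interval consistent with ten frames per bracket over a 2-h run.

The benchmark condition (`default_two_region_scene()`) renders a
128 × 128 px pouch at 1 µm/px — coarser than the 0.22 µm/px of a 60×/EMCCD
system, chosen so the full nine-ROI scheme fits a tractable image; pixel
size is plumbing that cancels out of every formula. Organizer regions
decay with $t_{1/2} = 45$ min, non-organizer with 30 min, both with
$n = -2.3$ and plateau 0.6 over the 0.2827 floor, matching the regional
contrast reported for OxPhos inhibition. The pixel noise SD (335 ADU on a
total intensity of 2000) is set so a single 20-µm ROI trace has an
efficiency SD of ≈ 0.005 per frame: after $5\times5$ smoothing and
averaging over a ROI, pixel noise $\sigma$ propagates to the trace roughly
as $\sigma\sqrt{(1-\eta)^2 + (\beta + \eta(1-\beta))^2}\,/\,(T\sqrt{A})$
with $A$ the number of effectively independent pixels, and the chosen SD
was verified by simulation. Baseline offsets (1500/1520 ADU) sit several
noise SDs above zero so rendered counts remain valid 16-bit camera
integers.

## Statistics

Region comparisons on fitted parameters use the standard two-sided tests —
Kruskal–Wallis (as in the published organizer/non-organizer comparisons,
even where the data are paired by disc; paired alternatives are available
in `compare_fits()`), Mann–Whitney, Welch and paired $t$ — delegating to
R's `kruskal.test`, `wilcox.test` and `t.test`. The estimation-plot
statistic is the unpaired mean difference with its Welch–Satterthwaite 95%
interval. The test suite carries exhaustive-permutation oracles: the
Mann–Whitney exact p equals enumeration over all arrangements at
$n \le 6$, and the Kruskal–Wallis $H$ equals the hand-ranked formula; the
chi-square p-value attached to $H$ is asymptotic and visibly approximate
at $n = 3 + 3$ (errors up to ~0.17 against the exact permutation p), which
is why no numerical agreement between the two is claimed at that sample
size.

## Problem sizes used in validation

The shipped analyses and tests run, by choice, at: a 26-disc end-to-end
cohort of the benchmark scene for the organizer contrast (Kruskal–Wallis
on per-disc half-lives); 100 seeded 26-disc cohorts at trace level for the
equal-kinetics null calibration (expecting $p > 0.05$ in ≥ 90% of runs);
noiseless 120-point traces plus 20 noisy replicates (trace SD 0.005) for
parameter recovery at each published operating point (half-lives 33, 42
and 96.7 min; Hill coefficients −1.8, −2.3, −3, −4.5, −4.57); and a
100,000-sample Gaussian draw (mean 0.3500, SD 0.03365) for the floor
calibration. Trace-level simulation is used for the null repeats because
the question there is purely about the fitter/test chain; the image path
is exercised end to end in the cohort run and the round-trip suites.

## Known limitations

* No drift/registration correction and no automatic boundary detection:
  landmarks are inputs, as in the original workflow where boundaries are
  identified by eye from the cpVenus channel.
* The identifiability flag on $t_{1/2}$ is a binary warning, not a
  confidence interval; mechanistic (ODE) models of ATP production and
  consumption are out of scope.
* Acceptor-photobleaching and lifetime-based FRET calibrations are not
  supported; the pipeline is specific to sensitized emission with a
  donor-only bleedthrough calibration.
* The synthetic benchmark shares one kinetic truth across discs, so
  between-disc variance in the cohort comes from noise alone; real
  cohorts add biological variability, which the rank-based comparisons
  tolerate but the generator does not emulate.
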