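---
title: "Methods: behavioral aging analysis for chamber-housed C. elegans"
author: "wormspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral aging analysis for chamber-housed C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormspan)
```

# Overview

`wormspan` analyzes long-term recordings of *C. elegans* housed one animal
per circular microfluidic chamber. Short grayscale clips (nominally 10 s at
14 fps, taken twice an hour) are reduced to four per-clip behavioral
metrics; the metric time series are scored for death, split into high- and
low-activity phases, summarized as population survival statistics, and used
to predict individual lifespan from early-life behavior. Because raw
recordings are rarely portable, the package ships a synthetic-data module
that renders ground-truthed worm clips and simulates ground-truthed aging
cohorts, so the complete pipeline is testable end to end without any real
video.

The stages, and the functions that implement them:

1. **Synthetic ground truth** — `worm_pose()`, `render_frame()`,
   `generate_clip()`, `generate_cohort()`, `run_synthetic_pipeline()`.
2. **Clip I/O and chamber geometry** — `load_stack()`, `detect_chambers()`,
   `crop_chamber()`.
3. **Consensus segmentation** — `candidate_masks()`, `consensus_segment()`,
   `update_prior()`, `skeletonize_mask()`.
4. **Behavioral metrics** — `raw_movement()`, `centroid_speed()`,
   `body_amplitude()`, `swim_frequency()`, `assemble_traces()`.
5. **Lifespan scoring** — `call_death()`, `call_deaths()`,
   `apply_censoring()`.
6. **Healthspan analysis** — `classify_phases_kmeans()`,
   `classify_phases_moving_average()`, `define_cohorts()`,
   `relative_trajectory()`, `trajectory_pca()`, `compare_cohort_decline()`.
7. **Population statistics** — `kaplan_meier()`, `mean_sem()`, `logrank()`,
   `anova_tukey()`, `healthspan_lifespan_correlation()`.
8. **Lifespan prediction** — `build_features()`, `censor_and_impute()`,
   `fit_lasso_cv()`, `transfer_residuals()`.

Conventions used everywhere: images are matrices of \[0, 1\] intensities
quantized to 8-bit levels; pixel coordinates are 1-based `(row, col)` with
the origin top-left; gray-level parameters are on the 0–255 scale; trace
time is in days (24 h/day), within-clip time in seconds.

# The synthetic-data model

## Rendered clips

A worm is a stadium-shaped band of half-width `body_width/2` around a
single-wavelength sinusoidal centerline whose arc length equals
`body_length`; this is the simplest shape with a well-defined skeleton,
bend amplitude and undulation phase. The worm is rendered dark on a bright
chamber disk (the chamber's `background_intensity` stands in for food
turbidity) over a dark surround, with a 1-px anti-aliased edge, additive
Gaussian sensor noise of SD `noise_sd` gray levels clipped to range, and
8-bit quantization. Undulation advances the phase by
$2\pi f/\mathrm{fps}$ per frame and the body midpoint follows a linear
drift; every frame's true pose is returned with the clip, so downstream
recovery tests always compare against generating parameters, never against
re-derived values.

The renderer does **not** attempt photorealism: no 3-D posture, no
progeny or eggs, no bacterial aggregates, no illumination gradients.
Passing tests on these clips demonstrate correctness of the geometry and
signal-processing chain, not robustness to every real-world imaging
artifact.

## Simulated aging cohorts

Each individual follows a two-phase `aging_profile()`: activity at
`high_level` (Gaussian noise, floored at half the low level so live
samples stay positive) until `high_activity_end`, then sporadic movement
until `death_time` — each low-phase sample shows movement at `low_level`
with probability `low_burst_prob` — and exactly zero strictly after death.
The exact-zero support after death is deliberate: it makes death-call
tests exact rather than approximate.

The field describes the late phase only as "sporadic low activity"; the
Bernoulli burst model is a stand-in, its parameters exposed rather than
asserted. Two regimes matter for testing:

* `low_burst_prob = 1` — continuous low-level movement until death. Death
  is then recoverable *exactly* (to the sampling grid), and this is the
  regime meant by "burst-free" recovery throughout the tests.
* `low_burst_prob < 1` — movement gaps before death; the cessation rule
  can only recover the last burst, so calls carry a quantization error on
  the order of half a sampling interval at `low_burst_prob = 0.5`.

Default cohort parameters are chosen as realistic wild-type conditions at
25 °C: lognormal lifespans with mean 18 d and CV 25%, a high-activity
phase ending at a Beta(8, 4) fraction of life (mean 2/3), high/low levels
1.0/0.1, sampling every 12 h.

# Chamber detection and cropping

Chambers are fixed-geometry, high-contrast bright disks, so detection uses
a circular-edge accumulator: the gradient magnitude (central differences)
is convolved with an annulus of the expected radius; accumulator peaks
approximate circle-edge contrast and are accepted above a threshold tied
to the image's intensity scale, refined to sub-pixel position by a local
weighted centroid, and filtered by an interior-brighter-than-exterior
contrast check. Ordering is row-major by center, which makes chamber IDs a
pure function of device geometry and therefore stable across clips. A
radius prior off by a factor of ~3 finds no peaks and raises a detection
error rather than returning a spurious layout.

Cropping takes the square circumscribing the circle plus a 2-px margin and
masks pixels outside the circle to the chamber's median interior
intensity, so frame differencing outside the chamber is exactly zero.

# Consensus segmentation

The segmentation contract is a *consensus*: candidates are cheap and
pluggable, the scorer and the temporal chaining are the fixed part.

* **Candidates**: dark connected components under several thresholds
  (Otsu on the chamber interior plus the 1%, 3% and 8% interior-intensity
  quantiles), deduplicated at IoU > 0.85.
* **Morphology score**: geometric mean of soft interval memberships for
  area, rod-equivalent length (from the pixel-scatter principal axes) and
  aspect ratio, each 1 inside the prior's range and decaying
  exponentially outside (scale = a quarter of the interval half-width),
  multiplied by a darkness term that reaches full weight at 20 gray
  levels of contrast below the interior median. The darkness term is what
  separates true worms from threshold speckle in empty chambers.
* **Continuity**: a quadratic penalty on the centroid jump between
  consecutive accepted frames, normalized by chamber radius (weight 1.0
  by default). The per-clip choice maximizes total morphology score minus
  penalties by dynamic programming; ties break deterministically by
  score, then smaller displacement, then lower candidate index.
* **Missing frames**: frames with no candidate above the acceptance score
  (default 0.2) are flagged `missing` and excluded from priors and
  metrics — never fabricated. An all-missing observation is legal and is
  treated downstream as zero movement.
* **Prior updates**: ranges move toward the clip's observed statistics by
  an exponentially weighted blend (`update_weight` 0.2 by default; 0
  freezes the prior, 1 adopts the clip), and the last accepted centroid
  anchors the next clip. Worms shrink and change optical density with
  age; the update weight controls how fast the prior follows.

Centerlines come from Zhang–Suen thinning followed by longest-path
extraction on the 8-connected skeleton graph (double breadth-first
search). Skeleton ends are extended along the local tangent to the mask
boundary — thinning retracts endpoints by roughly half the body width —
and the path is lightly smoothed before arc-length resampling, since
pixel-lattice jaggedness otherwise inflates arc length by several percent.
Masks whose skeleton has no endpoints (loop topology, e.g. an omega-turn
touching itself or a round blob) are flagged and contribute no centerline
for that frame. Head/tail identity is not resolved — no metric here needs
it — but orientation is kept consistent within a clip by matching
endpoints to the previous frame.

# Behavioral metrics

* **Raw movement**: the fraction of chamber pixels whose absolute
  intensity change between consecutive frames exceeds `diff_threshold`
  (default 10 gray levels), averaged over valid frame pairs. On 8-bit
  data the comparison uses a half-level guard band, so "more than 10
  levels" means at least 11. Raw movement is computed on the full chamber
  crop rather than the mask so it stays defined when segmentation fails —
  the death call depends on that. Normalizing by chamber area makes
  values comparable across crop sizes; absolute values are
  platform-specific and only relative/ordinal behavior is asserted.
* **Centroid speed**: mean consecutive-centroid displacement × fps over
  adjacent accepted frames; pairs spanning a missing frame are excluded.
  Reported in px/s, or µm/s when a pixel size is supplied (the device
  field of view fixes µm/px; it is a configuration scalar, not something
  the package guesses).
* **Body-bend amplitude**: per frame, the maximum perpendicular deviation
  of the centerline from its endpoint chord divided by centerline arc
  length; clip value is the mean over frames with valid centerlines. A
  semicircular posture gives the closed-form value $1/\pi$, which the
  tests use as a geometry oracle.
* **Swimming frequency**: the mid-body bend angle (angle between the
  anterior and posterior half-chords) over the longest contiguous run of
  frames with valid centerlines; after mean removal, the dominant
  frequency is the magnitude-spectrum peak, with resolution ≈ 1/run
  duration (0.1 Hz for a full 10 s clip) and a Nyquist cap. A single
  mid-body angle is used instead of full curvature modes because it is
  robust at 14 fps with imperfect skeletons; series with SD below 0.02
  rad are treated as flat and return 0.

Traces are assembled per individual on a 12-h analysis grid (nearest clip
within half an interval), with censored individuals dropped and duplicate
(chamber, timestamp, label) combinations rejected. Clips taken under
constant versus pulsed flow are distinguished only by a pass-through
label; flow itself is not modeled.

# Lifespan scoring

Death is called at the time of the last sample above the activity
threshold, provided every later sample stays at or below it and the trace
extends at least two days past that time (the confirmation window).
Individuals whose trace ends sooner are alive/undetermined and are
right-censored at their last sample; traces that never move are flagged
for manual review. Reporting the *last-movement* time (not the window
end) is a deliberate convention; the midpoint alternative can be obtained
by adding half the confirmation window.

The threshold is 0 for noise-free traces. For video-derived traces the
detection floor is estimated from verified-empty chambers as the 95th
percentile of their raw-movement values, times a fixed 2× margin. The
margin is needed because post-mortem clips are draws from the same noise
distribution as empty-chamber clips: by construction ~5% of them would
exceed the unscaled 95th percentile, and a single such excursion after
death would move the call. With the margin, the noise floor
(~5 × 10⁻⁴) sits far below the slowest live movement (~5 × 10⁻³ for a
barely-drifting worm), so the separation is about an order of magnitude.

Censoring follows the standard rules: multi-occupancy chambers and
non-aging deaths (vulval bursting) are censored with reasons; censored
individuals are excluded from mean ± SEM summaries but retained in
Kaplan–Meier estimation with censor flags.

# Healthspan analysis

Two classifiers, matched to how cleanly a metric separates:

* **Pooled k-means (k = 2)** for raw movement, centroid speed and
  swimming frequency: all sample values of one experimental condition are
  pooled and clustered (10 restarts, fixed seed; deterministic and
  invariant to label permutation since "high" is defined by the larger
  cluster mean). An individual's high-activity phase ends at its last
  high-assigned sample. An optional debounce ignores isolated short high
  runs that follow three or more consecutive low samples — sporadic
  late-life bursts otherwise inflate healthspan — but it is off by
  default so that exactness tests stay exact.
* **Moving average vs whole-life mean** for subtle metrics (body
  amplitude): the high phase ends at the first sample whose centered
  moving average (window 5 samples = 2.5 d at 12-h sampling; no window is
  canonical, this is the package default) falls below the individual's
  whole-life mean and stays below through trace end. Constant traces
  never cross and are flagged with the whole life counted as high. The
  k-means rule reports the last high sample, the moving-average rule the
  first below-crossing sample; the two conventions differ by at most one
  sampling interval.

Cohorts within a condition are the bottom and top 20th percentiles of
uncensored lifespan, ties at the boundary included. Relative trajectories
average each metric over 11 equal bins of the individual's own normalized
lifespan; empty bins are linearly interpolated between neighbors (nearest
value at the ends). Trajectory PCA is column-centered without variance
scaling, matching the convention of PCA "on raw data"; scores are defined
up to sign. Cohort decline is compared with a two-sample
Kolmogorov–Smirnov test, by default on the pooled distribution of bin
values (a per-bin mode is available and documented in the return shape).

# Population statistics

Kaplan–Meier estimation, the log-rank test, one-way ANOVA with Tukey's
HSD (Tukey–Kramer under unequal n) and Pearson correlations are delegated
to the `survival` package and base R; the module fixes the conventions —
mean ± SEM over uncensored individuals only, KM retaining censored
records, correlation of both high-activity duration and life-fraction
against lifespan with zero-variance cases flagged rather than silently
NaN — and the serialized output shapes. Tests verify the implementations
against hand-computed product-limit tables, a hand-coded log-rank
statistic, and the two-group F = t² identity, so the package's use of the
libraries is itself under test.

# Lifespan prediction

The feature table contains, for every metric × clip label × day, the
daily maximum and daily mean (samples in \[day, day + 1)), plus one
early-life decline slope per metric × label (least-squares slope over
adulthood days 1–10 by default; "rate of decline" has no canonical
window, so it is configurable). With four metrics, two flow labels and a
30-day grid this yields 488 named columns, and more than 500 once the day
grid covers the longest-lived condition. Column names follow the grammar
`metric.stat.dayNN.label` so a table is fully reconstructible from its
header. Features after an individual's death are missing — never zero —
and the death day contributes its partial samples.

Columns whose missing fraction exceeds 0.5 are censored (sparse columns
mostly reflect unreliable segmentation); remaining missing entries are
imputed with the column median. The LASSO is fit with `glmnet`:
features standardized before penalization, a 10-fold CV with fold
assignment a deterministic function of the seed, penalty chosen to
minimize mean CV error (the sparser 1-SE rule is exposed as an option),
out-of-fold predictions retained, and the final model refit on all data
at the chosen penalty. Transfer to another condition aligns columns to
the training schema (absent columns filled with training medians) and
summarizes signed residuals (predicted − observed) with a one-sided sign
test: systematic overestimation of a short-lived condition, or
underestimation of a long-lived one, shows up as a significant sign bias.

# Numerical choices and degenerate inputs

* 8-bit quantization everywhere; intensity thresholds carry a half-level
  guard band so float jitter cannot flip a comparison.
* All stochastic steps (rendering noise, cohort draws, k-means restarts,
  CV folds) consume locally scoped RNG streams derived from explicit
  seeds; outputs are pure functions of (parameters, seed) and the
  caller's RNG state is never disturbed.
* Degenerate inputs fail loudly and specifically: poses outside the
  chamber name the violating point; all-equal pooled activity refuses
  k-means; all-censored record sets refuse Kaplan–Meier; constant
  responses refuse the LASSO; loop-topology masks are flagged rather than
  given an arbitrary centerline.
* Tie-breaks are deterministic by construction (consensus choice: score,
  then displacement, then index; cohort boundaries include all ties).

# Problem sizes used in the shipped checks

The package's own verification runs at sizes chosen to exercise every
stage while staying comfortably interactive: the end-to-end video suite
renders 20 individuals × 40 timepoints of 6-frame, 128-px clips (about
five frame pairs per clip are enough for stable raw movement; full 140
frame clips are used where spectral resolution matters), cohort
simulations use 50–200 individuals, and the LASSO recovery design is
n = 200 × p = 500 with two informative features. The acceptance script
(`scripts/acceptance.R`) re-runs these computations from scratch at the
same sizes.

# Known limitations

* Raw-movement values are platform-relative; no absolute calibration is
  attempted or asserted.
* The renderer's simplicity means segmentation robustness to debris,
  illumination drift and progeny is untested here; the consensus scorer
  is designed for those failure modes (that is what the priors and the
  missing-frame discipline are for) but only field data can validate it.
* The burst model for late-life activity is a stand-in; conclusions that
  depend on the temporal statistics of low-phase movement should treat
  `low_burst_prob` as a sensitivity parameter.
* Multi-worm chambers are censored, not tracked; AVI containers are not
  read (convert to multi-page TIFF).
* The mixed-model decomposition of variance across trials and devices is
  out of scope; lifespan tables exported by this package can be fed to
  external mixed-model tooling.
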