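---
title: "Methods: from raw gaze samples to social-attention statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw gaze samples to social-attention statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When people freely view naturalistic photographs, how strongly is their
gaze driven by low-level physical saliency (local contrast in color,
intensity, orientation) versus social content (other people's heads and
bodies)? `socialgaze` implements a complete analysis chain for
free-viewing experiments that contrast scenes containing people with
carefully matched scenes that do not: saliency-fixation correspondence
metrics, region-of-interest (ROI) gaze scoring, the time course of the
first few fixations, and a scene-patch mixed-model analysis that pits
saliency, social features and central bias against each other in one
regression.

The package assumes the canonical setup: stimuli of 1,200 x 900 px
subtending 32.5 x 24.7 degrees at a fixed viewing distance (30.6 x 23.0 cm
at 52.5 cm), monocular gaze sampled at 1,000 Hz, trials of 10 s preceded by
a central fixation cross. All of these are parameters
(`viewing_geometry()`, `cohort_config()`), not constants.

## Pipeline stages and their models

### Event detection (`detect_events`)

Saccades are samples whose instantaneous velocity exceeds 30 deg/s or
whose acceleration exceeds 8,000 deg/s^2; fixations are the maximal
stationary runs between them; blinks are runs of missing pupil data. A
trial is valid only when its total blink time during scene presentation is
under 2 s. Velocity and acceleration are estimated by central differences
over a 5-sample window — the exact filter inside commercial parsers is
unpublished, so this documented estimator is used and is configurable.
Stationary runs shorter than 40 ms are left unclassified rather than
promoted to fixations (a common jitter guard; the threshold is an
argument). Fixations that started before scene onset are not scene
fixations (the observer was still on the cross), and fixations straddling
scene offset are truncated at the offset.

### Drift correction (`compute_baselines`, `drift_correct`)

Slow calibration drift is removed per trial using the mean gaze position
during the 300 ms before scene onset, when the central cross was fixated.
Baselines distorted because the observer did not actually fixate the cross
are screened per participant with a recursive outlier rule: repeatedly,
the distribution's minimum and maximum are tested against the mean +/- 3
SD of the distribution with both extremes removed, and any extreme beyond
the bound is discarded permanently. Flagged or missing baselines are
replaced by the mean of the participant's valid baselines, and the trial
is marked `baseline_replaced` (such trials are excluded from the
early-fixation analyses, where the starting position matters). Every
fixation is shifted by `cross - baseline`; the sign convention is chosen
so a trial whose baseline sits exactly on the cross is unchanged. The
baseline is the mean of raw samples inside fixation periods, not of
fixation centroids; the two interpretations differ negligibly but the
sample-average one is implemented. The SD in the outlier rule uses the
n - 1 denominator.

### Fixation density maps (`build_density_map`)

Each fixation's duration in ms is added at its rounded pixel position,
and the impulse map is smoothed with an isotropic Gaussian (sigma = 36 px,
about 1 degree, so +/- 2 sigma resembles the foveal field) and min-max
normalized to [0, 1]. The conventional round constants — 36 px for sigma
and 72 px for the 2-degree window — are used literally rather than
recomputing 1200/32.5 = 36.9 px/deg, matching how such pipelines are
usually reported. The smoothing is
computed as a direct sum of 4-sigma-truncated kernels placed at the
fixation pixels, which is exactly the zero-padded convolution of the
impulse accumulator but two orders of magnitude faster for ~30 impulses.
Zero padding means mass near borders is attenuated, not reflected; min-max
normalization absorbs the scale.

### Saliency (`compute_reference_saliency`, `load_saliency_map`)

The analysis treats the saliency model as pluggable: maps from any
external model can be loaded from float TIFF or text matrices and are
min-max rescaled to [0, 1]. A documented reference implementation in the
Itti-Koch style is included (intensity, R-G and B-Y opponency, four
orientation-energy channels; difference-of-Gaussians band-passes at 4
dyadic scales; per-channel max normalization; equal-weight average;
optional explicit Gaussian center bias, off by default since the patch
models include center distance as a predictor). It is a transparent
stand-in, not a benchmark-grade model; the package's scientific content is
downstream of whatever saliency map is supplied.

### Map comparison (`compare_maps`)

Three metrics per participant x scene: the Kullback-Leibler divergence
D(F || S) of the sum-normalized density F from the sum-normalized
saliency S (how badly saliency describes where gaze actually went), the
AUC for predicting above-mean-density pixels from saliency scores
(midrank Mann-Whitney; 0.5 is chance), and the Pearson correlation of the
two normalized maps. Both maps receive an epsilon of 1e-12 per cell before
normalization; results are stable for epsilon between 1e-15 and 1e-9. The
KL direction and log base are not universal conventions, so both are
arguments (`log_base = exp(1)` reports nats). A constant saliency map
yields AUC 0.5 by convention and r reported as 0 with `r_defined = FALSE`.

### ROI analysis (`build_roi_set`, `roi_relative_saliency`, `roi_norm_fixation_density`)

Social scenes are partitioned into head, body (minus head), and — among
the remaining pixels — lower- and higher-saliency regions split at the
80th saliency percentile (ties go to the lower region; the percentile uses
interpolated quantiles by default, a sample order statistic via
`quantile_type = 1`). Relative saliency is the ROI mean over the scene
mean; relative area-normalized fixation density is the ROI's share of
density divided by its share of scene area, so a uniform density scores
exactly 1 in every ROI and the area-weighted mean across ROIs is exactly 1.
"Area" is the dimensionless scene fraction; any constant unit choice
cancels in comparisons.

### Time course (`fixation_window_saliency`, `ranked_saliency_table`, `ranked_roi_frequencies`)

For the first five fixations (plus a pooled "6+" bin), relative saliency
is the mean saliency in a circular 2-degree (72 px) window around the
fixation, over the scene mean; ROI hits are the label of the fixated
pixel. ROI hit frequencies are normalized by the mean area fraction of the
ROI across exactly the scenes represented in the participant x rank cell.
Off-image fixations carry no ROI label and are excluded from both numerator
and denominator (the alternative — counting them in the denominator — is a
documented choice we did not take). Baseline-replaced trials are excluded
throughout this stage.

### Scene patches and mixed models (`patchify`, `fit_mixed_model`, `compare_models`)

Each scene is divided into a 12 x 9 grid of 100 x 100 px patches (108
records per participant x scene). Patch features — relative fixation
density, relative saliency, relative head and body coverage — are each
divided by the scene-wide mean of patch values, so their per-scene mean is
exactly 1; scenes with no head pixels get `rel_head = 0` everywhere,
flagged. Distance from center takes exactly 27 distinct values on this
grid (minimum 50 px). Predictors are standardized to mean 0, SD 1 over the
pooled table; interaction columns are products of the standardized mains
and are not re-standardized (a documented choice; the alternative changes
coefficients by a constant factor only).

The model ladder 1a..6 regresses relative patch density on growing
fixed-effect sets with crossed random intercepts for participant and
scene. Fitting uses lme4 with the bobyqa optimizer: REML estimates for
coefficients (Satterthwaite p-values via lmerTest where available, Wald-z
otherwise — at ~2.6e5 rows the difference is negligible; the method used
is recorded in the fit), ML refits for likelihood-ratio tests and AIC.
The goodness-of-fit analog is the squared correlation between observed and
fitted values. Decile-bin summaries per predictor use empirical quantile
bins; head/body get a zero-coverage bin plus deciles over covered patches,
and center-distance bins are uneven (about 7-13% each) because of the 27
distinct values.

### Repeated-measures statistics (`rm_anova`, `paired_t`, `bonferroni_posthoc`)

The within-subject ANOVA uses the univariate sums-of-squares decomposition
with the participant x factor interaction as each effect's error stratum
(this reproduces the classical df such as F[4,120] and F[12,360] for a
5 x 4 design with 31 participants). Huynh-Feldt's epsilon is estimated
from the covariance of orthonormal contrast scores and applied to both
degrees of freedom whenever the numerator df exceeds 1; a two-level factor
has epsilon = 1 identically. Partial eta squared is
SS_effect / (SS_effect + SS_error). Cohen's d for paired data defaults to
d_z = mean(diff)/SD(diff); the pooled-SD variant is available via
`d_method = "pooled"`. Post hoc paired t-tests use a Bonferroni threshold
alpha/m (0.05/6 = 0.0083 for four conditions).

## The synthetic cohort

No public gaze recordings accompany this design, so `generate_cohort()`
produces a fully seeded cohort with the study's structure: 31 participants,
80 social + 80 non-social scenes, 10-s trials, ~31 fixations per trial with
mean duration 277 ms (SD 48, truncated at 40 ms), saccade amplitudes
~Normal(4.7, 1.0) degrees, per-trial constant drift (SD 6 px), occasional
long blinks (1.3% of trials exceed the 2-s rule) and occasional off-cross
baselines (4%) for the outlier screen to catch.

Scenes are constructed, not photographed: the saliency map is built
directly (background floor plus dense mid-level texture, a central
elevation emulating the central bias of screen-based saliency maps, and
10-14 strong distractor blobs concentrated around 6-7 degrees from
center), so the stimulus properties hold by design. Social scenes place an
elliptical head (2.15% of the scene) and body (8.95%) about 9.6 degrees
from center; their saliency is pinned at exactly 1.2x the scene mean with
a radial gradation — salient contours, low-saliency interiors — because
contrast-driven models highlight the outline of a person, not the face
people actually fixate.

The scanpath model starts on the (pre-onset) cross fixation; rank 1 is the
landing of the first saccade after a ~200 ms latency. Each saccade draws a
target in two stages: first exploration vs guided, with the exploration
share computed from the same full budget in both scene categories (so
social and non-social trials wander equally — this matters for the paired
metric contrasts); then, within guided, head / body / saliency components
on social scenes (saliency only on non-social scenes). Rank schedules make
early fixations saliency-seeking (decreasing weight and sampling-sharpness
schedules) and boost the head weight on ranks 1-3; saccade amplitudes are
truncated toward the target, so a head 9.6 degrees away is typically
reached on the second saccade — the mechanism behind the rank-2 peak in
head fixation frequency. Unreached targets persist to the next saccade,
recently fixated spots are avoided (inhibition of return), and social
targets cluster on the region's focal center.

What the generator does *not* emulate: photorealistic image content,
microsaccades, smooth pursuit, pupil dynamics beyond a validity flag,
oculomotor noise beyond isotropic jitter, and any between-participant
individual differences in social preference. Passing tests on this cohort
therefore demonstrate that the pipeline measures what it claims on data
with known ground truth — not that any particular empirical effect size in
real data is reproduced.

## Problem sizes used by the test suite

The packaged tests exercise the full pipeline on a 12-participant,
30 + 30-scene cohort (seed 1) — large enough that every qualitative
contrast is decisive, small enough to run in minutes. Mixed-model
parameter recovery runs at the full ~264,000-row scale with 3 replicates;
2-SE coverage is compared against its nominal 95% rate with a one-sided
binomial allowance for the finite number of checks. The ANOVA type-I-error
property uses 1,000 AR(1)-correlated null replicates. `scripts/acceptance.R`
re-runs the chance-level AUC experiment (1,000 pairs of 64 x 64 maps) and
the cohort pipeline from scratch at these same sizes.

## Known limitations

* The reference saliency model is a transparent center-surround
  implementation, not a tuned benchmark model; use `load_saliency_map()`
  for serious saliency comparisons.
* `rm_anova` handles fully within-subject, balanced one- and two-factor
  designs only; incomplete designs are dropped listwise with a warning.
* The KL direction and log base must match whatever convention you compare
  against; both are explicit arguments.
* Fixation-level shortcuts in the generator (blink totals drawn per trial
  rather than placed within the trace) mean the 2-s validity rule is only
  exercised end-to-end in the sample-level path.
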