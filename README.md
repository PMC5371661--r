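# socialgaze

Social attention versus physical saliency in free-viewing eye-tracking
data.

When observers freely view naturalistic scenes, low-level saliency models
(contrast in color, intensity, orientation) predict gaze reasonably well —
until other people are in the picture. `socialgaze` implements the full
analysis chain for experiments that contrast social with non-social
scenes, quantifying how strongly gaze is drawn to heads and bodies over
and above what physical saliency and the central fixation bias explain.

The pipeline, from raw 1,000-Hz gaze samples to inferential statistics:

* **Event detection** — saccades by velocity/acceleration thresholds
  (30°/s, 8,000°/s²), fixations as inter-saccade runs, blinks as missing
  pupil data; trials with ≥ 2 s of blink time are invalid.
* **Drift correction** — per-trial baselines from the 300 ms pre-onset
  cross fixation, screened per participant by recursive ±3 SD outlier
  removal.
* **Fixation density maps** — duration-weighted impulses smoothed with an
  isotropic Gaussian (σ = 36 px ≈ 1°), normalized to [0, 1].
* **Saliency–fixation correspondence** — Kullback–Leibler divergence
  D(F‖S), ROC AUC for above-mean-density pixels scored by saliency, and
  pixelwise Pearson *r*; per-participant means contrasted between scene
  categories by paired *t*-tests with Cohen's *d*.
* **ROI analysis** — head / body / lower-saliency / higher-saliency
  partition (80th-percentile saliency split of non-social pixels),
  relative saliency and area-normalized fixation density per region.
* **Time course** — foveal-window (2°) relative saliency and
  area-normalized ROI hit frequencies for fixations 1–5 (+ a "6+" bin).
* **Scene-patch mixed models** — a 12 × 9 grid of 100-px patches; relative
  patch fixation density regressed on center distance, saliency, head and
  body coverage (standardized) with crossed random intercepts for
  participant and scene (lme4/lmerTest); incremental likelihood-ratio
  tests and AIC across the model ladder 1a…6; decile-bin summaries.
* **Repeated-measures statistics** — one- and two-way within-subject
  ANOVA with Huynh–Feldt ε, partial η², Bonferroni post hocs, paired
  effect sizes.
* **Synthetic cohort generator** — seeded scenes (constructed saliency
  with pinned social-region properties), scanpaths and raw 1,000-Hz
  traces with known ground truth, so every stage is testable without
  external recordings.

## Worked example

```r
library(socialgaze)

geom <- viewing_geometry()
geom
#> <viewing_geometry> 30.6 x 23.0 cm @ 52.5 cm -> 32.5 x 24.7 deg;
#>   1200 x 900 px (36.93 px/deg horizontal)

scene <- generate_scene(scene_spec("social"), seed = 7)
rois  <- build_roi_set(scene$head_mask, scene$body_mask, scene$saliency)
rois
#> <roi_set> area fractions: head 0.021, body 0.089, lower 0.712, higher 0.178

roi_relative_saliency(rois, scene$saliency)
#>   roi    rel_saliency defined
#> 1 head          1.20  TRUE
#> 2 body          1.20  TRUE
#> 3 lower         0.679 TRUE
#> 4 higher        2.16  TRUE
```

The social regions sit at intermediate saliency (1.2× the scene mean),
between the lower- (0.68) and higher-saliency (2.16) regions — the
stimulus property that lets social attention be separated from saliency.
Now simulate one 10-s viewing and score it:

```r
fix  <- simulate_fixation_sequence(scene, gaze_model_params(), geom, seed = 7)
nrow(fix)                      # ~31 fixations in 10 s
#> [1] 32

dens <- build_density_map(fix, geom)
compare_maps(scene$saliency, dens)
#>    d_kl   auc     r r_defined
#> 1  1.40 0.724 0.139 TRUE

roi_norm_fixation_density(rois, dens)
#>   roi    proportion rel_norm_density
#> 1 head       0.0968            4.50
#> 2 body       0.459             5.16
#> 3 lower      0.238             0.335
#> 4 higher     0.206             1.16
```

The head region holds 2% of the scene but ~10% of the gaze (area-normalized
score 4.5); the lower-saliency region (71% of the scene) is strongly
avoided (0.34). A full cohort analysis — category contrasts, ANOVAs, the
mixed-model ladder and all result tables — is one call:

```r
cohort <- generate_cohort(cohort_config(n_participants = 12, n_social = 30,
                                        n_nonsocial = 30, seed = 1))
res <- analyze_cohort(cohort)
res$metric_tests       # paired social vs non-social tests for D_KL, AUC, r
res$roi_density_anova  # one-way rmANOVA with Huynh-Feldt correction
tidy(res$model_fits[["4"]])   # scene-patch mixed model coefficients
plot_time_course(res$ranked_saliency, res$ranked_roi)
```

`run_pipeline(pipeline_config(output_dir = "out", seed = 1))` does the same
and writes every table as CSV plus a manifest for reproducibility.

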