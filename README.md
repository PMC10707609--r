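# mrdeye

Automated measurement of **marginal reflex distance 1 (MRD1)** — the
vertical distance in millimetres from the pupil centre to the upper eyelid
margin — from close-up infrared (IR) eye images, together with the
method-agreement statistics used to validate automated ptosis measurement
against manual and photographic methods.

MRD1 grades ptosis severity (mild 3–4 mm, moderate 2–3 mm, severe 0–2 mm)
and drives eyelid-surgery decisions. IR imaging makes automation tractable:
the pupil is dark and cleanly separable from even a dark brown iris, which
is exactly where RGB photograph analysis fails. `mrdeye` is aimed at
researchers building or validating such instruments: it provides the full
measurement geometry, a classical segmenter plus an injection path for
neural segmentation masks, a synthetic renderer with exact ground truth for
testing, and the statistical battery of a clinical method-comparison study.

## What it computes

Given a single-eye IR image, the pipeline is

1. **Segmentation** into background (0), sclera (1), iris (2), pupil (3) —
   glint inpainting, median denoising, exact multi-level Otsu thresholding,
   and structural class assignment (`segment_ir_eye()`), or a mask you
   provide (`read_mask()`).
2. **Pupil circle** by the algebraic Kåsa least-squares fit
   min Σ(x² + y² + Dx + Ey + F)² over pupil rim pixels, with lid-occlusion
   chord pixels excluded so ptotic eyes don't bias the centre
   (`fit_pupil_circle()`).
3. **Upper lid margin**: first background run of ≥ k rows scanning up the
   pupil-centre column, at sub-pixel step-edge precision
   (`find_upper_lid_margin()`).
4. **Calibration** from a 5 mm fiducial dot on the lower-lid skin:
   px/mm = equivalent-area dot diameter / 5 (`detect_calibration_dot()`).
5. **MRD1** = (pupil centre row − margin row) / px·mm⁻¹, signed: positive
   when the margin is above the centre (`compute_mrd1()`, `measure_image()`).

For cohorts measured by several methods (manual penlight, deep-learning IR,
ImageJ on RGB/IR photographs), `apply_exclusions()` implements the six-rule
clinical filter and `agreement_report()` computes descriptives, one-way
ANOVA with Scheffé post hoc, Pearson correlations, Bland–Altman limits of
agreement (LOA = mean difference ± 1.96 sd; ΔLOA = upper − lower) and
per-pair regressions. Every moment-based statistic is also available
directly from printed summary tables — `anova_from_moments()`,
`scheffe_posthoc()`, `se_from_moments()`, `ci_from_moments()`,
`pool_moments()` — so a published study can be re-analysed without raw
patient data.

## Worked example

Render a synthetic eye with known ground truth (MRD1 = 3.2 mm, 12 px/mm,
pixel noise sd 8) and measure it:

```r
library(mrdeye)

r <- render_eye(eye_spec(upper_lid = lid_curve(3.2, 0.06),
                         noise_sd = 8, seed = 42))
measure_image(r$image)
#>     ok  mrd1_mm pupil_row_px pupil_col_px pupil_radius_px lid_margin_row_px px_per_mm
#> 1 TRUE 3.166349        240.5        320.5        24.02594             202.5   12.0012
```

The estimate is 3.166 mm against a 3.2 mm truth — within half a pixel
(1 px = 0.083 mm) under noise. The fitted pupil centre (row 240.5), margin
row (202.5) and dot-derived scale (12.0 px/mm) are all reported, with QC
flags for every failure mode (no pupil, no dot, lid over centre, ...).

Re-analyse a published four-method summary table from its printed moments:

```r
mm <- method_moments()        # n, mean, sd per method (56 eyes, 4 methods)
anova_from_moments(mm)
#>   term        ss  df    ms statistic p.value
#>   between   5.46   3  1.82      1.70   0.168
#>   within  236.   220  1.07
#>   total   241.   223
scheffe_posthoc(mm)[3, ]
#>   method1     method2    diff    se p.adj  ci_lo ci_hi
#>   mrd1_manual mrd1_rgb -0.433 0.196 0.182 -0.984 0.118
```

The four methods do not differ significantly (F = 1.70, p = 0.168), and the
largest pairwise gap (manual vs RGB, −0.43 mm) has a Scheffé interval
crossing zero.

Simulate a full four-method cohort and summarize agreement:

```r
tab <- generate_cohort(cohort_sim_spec(n_eyes = 56, seed = 1))
bland_altman(tab$mrd1_dl, tab$mrd1_ir)
#>    n mean_diff sd_diff loa_lo loa_hi delta_loa
#>   56    0.0630   0.441 -0.801  0.927      1.73
```

The DL − IR mean difference (0.063 mm) recovers the simulated bias offset
(0.20 − 0.14 = 0.06 mm). `plot_bland_altman()`, `plot_regression()`,
`plot_method_box()` and `autoplot()` draw the standard figures;
`tidy()`/`glance()` give broom-style views of a report.

A command-line interface wrapping the same functions lives at
`inst/cli/mrd1.R` with subcommands `simulate | segment | measure | agree |
run`; `run_pipeline()` executes the whole simulate → measure → agree chain
to disk, deterministically for a given seed.

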