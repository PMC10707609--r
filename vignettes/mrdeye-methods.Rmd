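---
title: "Measuring MRD1 from infrared eye images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring MRD1 from infrared eye images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdeye)
```

## The measurement problem

Marginal reflex distance 1 (MRD1) is the vertical distance, in millimetres,
from the centre of the pupillary light reflex to the upper eyelid margin with
the eye in primary gaze. It is the standard severity grade for ptosis
(drooping upper lid): roughly 3–4 mm is mild, 2–3 mm moderate, 0–2 mm severe.
Manual penlight measurement is quick but subjective and poorly repeatable at
the sub-millimetre scale where surgical decisions live. Near-infrared (IR)
photography makes automated measurement tractable because the pupil appears
dark and cleanly separated from even a dark brown iris — the precise failure
mode of RGB photographs.

`mrdeye` implements the automated side of this measurement and the
statistics used to validate it against other methods:

1. a **synthetic IR eye renderer** with exact ground truth,
2. a **four-class segmenter** (background 0, sclera 1, iris 2, pupil 3) with
   an injection path for masks produced by external (e.g. neural) models,
3. **calibrated geometry**: pupil-circle fit, upper-lid-margin localization,
   fiducial-dot pixel-to-mm scaling, signed distance,
4. a **method-agreement battery**: descriptives, one-way ANOVA with Scheffé
   post hoc, Pearson correlation, Bland–Altman limits of agreement, simple
   regression — each available both from raw data and from printed summary
   moments.

All modules share one coordinate convention: matrices are indexed
`[row, col]` with row 1 at the top and y increasing downward; the millimetre
frame is anchored at the image centre; **positive MRD1 means the lid margin
lies above the pupil centre**.

## The synthetic eye model

`eye_spec()` parameterizes a single-eye close-up: a pupil disk inside an
iris annulus, sclera filling the lid aperture, skin elsewhere, an optional
saturated glint, and a circular reference dot of known diameter (default
5 mm) on the lower-lid skin. Lid margins are parabolas in the mm frame with
apex at the pupil-centre column. The closed-form consequence that makes
the renderer useful for testing: the upper lid's apex offset *is* the
ground-truth MRD1, exactly, at any resolution.

Eyelid margins in photographs are not literally parabolic; the parabola was
chosen because it gives a closed-form margin position at every column while
capturing the qualitative shape (flat near the apex, closing at the canthi).
Defaults are 640×480 px at 12 px/mm, 8-bit grey, with class intensities
pupil 20, iris 90, skin 130, sclera 190 and dot 255 (0–255 scale) — values
chosen once for dark-pupil IR realism and satisfying the required ordering
pupil < iris < sclera. Gaussian pixel noise (`noise_sd`, grey levels) and a
seed complete the spec; renders are deterministic and quantized to 8 bits so
they round-trip PNG exactly.

Occlusion is drawn in anatomical order: lids clip iris and pupil; the glint
brightens the *image* only, because a reflection is still anatomically
pupil or iris — the truth mask keeps the underlying class. The dot is
clipped to skin.

What the renderer does **not** emulate: eyelashes, skin texture, iris
structure, off-axis gaze, shading gradients, motion blur. Passing tests on
synthetic renders therefore demonstrate correctness of the geometry and the
robustness logic, not clinical performance on patient photographs; the mask
injection path (`read_mask()`) exists precisely so externally produced
segmentations of real images can enter the same measurement geometry.

`cohort_sim_spec()` / `generate_cohort()` simulate the four-method
measurement design used in clinical validation: true MRD1 per eye drawn from
a normal distribution truncated at zero (clinically, eyes with MRD1 ≤ 0 are
excluded), observed by each method as truth + method bias + Gaussian error,
with the manual method averaged over three rater replicates. Defaults — truth
mean 2.84 mm, sd 1.0 mm; biases manual 0, DL +0.20, IR +0.14, RGB +0.43 mm;
error sd 0.3 mm — mirror the published 56-eye cohort's per-method means (see
`method_moments()`).

## Segmentation

`segment_ir_eye()` is a classical pipeline in fixed order:

1. **Glint inpainting** — saturated components (grey > 0.9) no larger than
   `glint_max_area_px` (default 300 px; the calibration dot is larger and
   survives) are filled with the median of a surrounding ring.
2. **Denoising** — an exact 3×3 median filter (vectorized sorting network).
   The pixel noise level is estimated from the scaled MAD of horizontal
   first differences, and one or two extra passes are applied above
   0.04 and 0.08 respectively, so heavy noise cannot hand the global
   thresholds to the broadened skin mode. Median passes preserve straight
   edges, which is why boundary accuracy survives smoothing.
3. **Multi-level Otsu** — three thresholds on a 256-bin histogram chosen by
   exhaustive maximization of between-class variance (exact, not a greedy
   approximation), yielding four intensity bands.
4. **Semantic assignment by structure** — the darkest band's largest opened
   component seeds the *eye region* (the dark component enclosing it,
   hole-filled). Pupil vs iris is then decided by a second, two-class Otsu
   *restricted to that region*: within the region the dark-pupil contrast
   dominates and the (much larger) skin population cannot bias the
   threshold. Sclera is seeded by brightest-band components adjacent to the
   region and grown with a threshold midway between the skin and sclera
   medians; the calibration dot is bright but never adjacent to the iris, so
   it stays background.

Failure is explicit: a flat image, a frame-filling dark region, or no dark
component reaching `min_pupil_area_px` (default 150 px) raises a
`pupil not found` condition — the machine-no-measurement failure mode that
cohort filtering maps to its exclusion rule. Ties between equally dark
candidates break toward the component nearest the eye-region centroid.

## Geometry

**Pupil circle.** `fit_pupil_circle()` uses the algebraic Kåsa form:
minimize \(\sum_i (x_i^2+y_i^2 + Dx_i + Ey_i + F)^2\) over boundary pixels
of the retained pupil component — a linear least-squares problem. Two
rasterization-aware details matter. First, boundary pixels whose
neighbourhood touches background are the *lid-occlusion chord*, not pupil
rim, and are excluded from the fit; without this the centre estimate drifts
downward exactly in the ptotic (small MRD1) case the instrument exists for.
The fit falls back to the full boundary if fewer than six rim points
survive, and fewer than six boundary points at all is an error. Second,
inner-boundary pixel centres sit on average half a pixel inside the true
circle, so the reported radius adds 0.5 px. The pupil centre comes from the
circle fit rather than the mask centroid for the same occlusion-robustness
reason.

**Lid margin.** `find_upper_lid_margin()` scans upward from the pupil-centre
row along the pupil-centre column; the margin is the first background row
starting a run of at least `k` consecutive background rows (default
`k = 3`, skipping single-pixel label noise), reported at sub-pixel
precision as the midpoint of the step edge — unbiased for an ideal step.
A background label at the pupil centre itself is the MRD1 ≤ 0 case and is
flagged (`lid_covers_pupil_center`) rather than measured; the geometry never
clamps, and negative distances from `compute_mrd1()` are returned signed
with a `margin_below_center` flag. MRD1 is measured along the vertical
column through the fitted centre — the clinical primary-gaze definition —
rather than as a nearest-point distance.

**Calibration.** `detect_calibration_dot()` finds saturated blobs with
circularity \(4\pi A/P^2 \ge 0.85\) inside an area window (defaults
200–50 000 px, i.e. dots from roughly 3 to 50 px/mm), requires exactly one,
and sets `px_per_mm` to the blob's equivalent-area diameter divided by the
nominal dot diameter. Zero or several candidates fail calibration and force
the no-dot QC path, where the caller supplies `px_per_mm` explicitly.

`measure_image()` composes segment → fit → margin → calibrate → distance
into a one-row tibble and converts every sub-operation failure into a
structured failure record with QC flags — a batch over hundreds of images
never crashes on one bad frame.

## Agreement statistics

The raw-data routes use standard machinery (`stats::lm`, `stats::cor.test`);
the package's contribution is the **moments-based** battery, which
re-analyses printed summary tables when raw patient data are unavailable:

* `anova_from_moments()`: \(SS_B = \sum n_i(\bar x_i - \bar x)^2\),
  \(SS_W = \sum (n_i - 1)s_i^2\), F and p from the F distribution.
* `scheffe_posthoc()`: pairwise difference, pooled standard error
  \(\sqrt{MS_W(1/n_i+1/n_j)}\), adjusted
  \(p = P\{F_{k-1,df_W} \ge (d/SE)^2/(k-1)\}\), simultaneous CI
  \(d \pm \sqrt{(k-1)F_{0.95;k-1,df_W}}\,SE\).
* `se_from_moments()`, `ci_from_moments()`, `pool_moments()` for
  descriptive rows and the pooled total row.
* Bland–Altman mean differences for pair (A, B) equal
  \(\bar A - \bar B\) and so are recoverable from means alone;
  limits of agreement are mean ± 1.96 × sd of differences, and ΔLOA is
  upper minus lower. The x − y sign convention is used throughout.

The moments route and the raw route are verified against each other to
10⁻¹⁰ on random cohorts in the test suite, and the identity R² = r² ties
the regression and correlation blocks together. `method_moments()` ships
the published 56-eye four-method summary (n, mean, sd per method) that the
moments battery reproduces to the printed precision (±0.002): F = 1.700,
Scheffé SE = 0.19557, pooled SD = 1.0397, and Bland–Altman mean differences
−0.4333 (manual − RGB) and 0.0611 (DL − IR).

`apply_exclusions()` implements the six-rule cohort filter (missing rater
replicates; manual ≤ 0; indistinct RGB boundary; |manual − reference| >
1 mm; no machine measurement; recent surgery). The clinical protocol does
not fix a rule ordering, so rules apply in order 1→6 with first-match
attribution,
making per-rule counts well defined and conservation (excluded + retained =
input) exact. Eyes are treated as independent observations and the ANOVA
treats methods as independent groups — both choices reproduce the published
analysis design; a paired or eye-within-patient mixed model is deliberately
out of scope.

## Numerical choices and degenerate inputs

* t and F quantiles at full double precision; no table lookups.
* Zero within-group variance with distinct means yields a flagged infinite
  F rather than an error; identical groups give F = 0, p = 1.
* Zero-variance columns make correlations undefined (`NA` + warning), not
  zero.
* Bland–Altman and regression require ≥ 2 and ≥ 3 complete pairs
  respectively; descriptives require n ≥ 2 for a variance.
* The LOA multiplier is fixed at 1.96 by default and exposed as a
  parameter.
* Mask PNGs store labels 0–3 directly as 8-bit values, so round-trips are
  lossless; 16-bit TIFF input is rescaled to [0, 1].

## Problem sizes used in validation

The shipped tests and the acceptance script validate at sizes chosen to
make sampling error negligible relative to the tolerances they check:
moments reproduction on the published 4 × 56 summary; oracle equivalence on
100 random cohorts; bias recovery on simulated cohorts of 10 000 eyes
(standard error of a mean difference ≈ 0.004 mm); and end-to-end geometric
recovery on 200 rendered eyes at 12 px/mm with pixel noise sd 8 and true
MRD1 spanning 0.5–5 mm, where the pipeline is required to land within
0.15 mm of truth for at least 95% of eyes and within one pixel-equivalent
(0.083 mm) for noiseless renders.

## Known limitations

* The classical segmenter assumes the IR intensity ordering
  pupil < iris < skin < sclera with usable contrast at each step; low-contrast
  or heavily vignetted captures should use the mask-injection path.
* Lid margins are localized on the segmentation's background border; eyelash
  shadows in real images will read as margin unless the upstream mask
  resolves them.
* One eye per image; binocular frames must be split by the caller.
* MRD2 and palpebral fissure height are not implemented.
* Published raw-data quantities that depend on per-eye covariance
  (Pearson r = 0.822, ΔLOA = 2.5162, regression slope 0.82) cannot be
  reproduced from summary moments; the package validates those code paths
  by property-based simulation instead.
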