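---
title: "Nuclear morphometry and discriminant grading: models and methods"
author: "nucmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and discriminant grading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Gleason grading of prostate adenocarcinoma is architectural: a pathologist
judges glandular patterns under the microscope. The decision that matters
clinically — pattern 3 (indolent, candidate for surveillance) versus
patterns 4–5 (treatment-requiring) — suffers from substantial
inter-observer variability. Computerized nuclear morphometry offers an
orthogonal, purely cellular signal: tumour-cell nuclei change in size,
boundary complexity, chromatin density and chromatin texture as grade
increases. This package implements that analysis end to end: a synthetic
image generator with grade-specific nuclear structure, a 38-descriptor
morphometric battery computed from a labeled image, univariate screening
across grade groups, and a 7-variable linear discriminant score with a
ROC-chosen operating point for the binary low/high-grade call.

Because no public image set accompanies the cohort this design is modelled
on, the synthetic generator is a first-class module: it is the test bed on
which every downstream stage is validated.

## The synthetic generator

A cohort (`cohort_spec()`, default 24/20/16 samples for grades 1–3, 4 and
5, 100 nuclei per sample) is rendered one *sample* at a time
(`render_scene()`). The hierarchy matters: published per-grade summary
tables report mean ± SD *across samples* of per-sample means, so each
profile SD in `grade_profile()` is a between-sample SD. Each scene first
draws sample-level parameters (mean minimal radius, boundary roughness,
mean R/G/B intensity), then scatters individual nuclei around them with
within-sample knobs (`radius_cv_within`, default CV 0.08, and per-pixel
chromatin noise `texture_sd`).

Nuclear outlines are star-convex radial perturbations,
$r(\theta) = r_0\,(1 + a\,z(\theta))$, with $z$ a zero-mean sum of random
Fourier harmonics (wavenumbers 2–9, $1/k$ amplitude decay) rescaled so
$\max|z| = 1$; the radial deviation is therefore bounded by $a\,r_0$
exactly and the shape stays star-convex.

Two structural choices are derived from the published per-grade table
rather than left free:

* **Radius semantics.** The profile radius is the target *measured minimal
  radius* (3.36/3.63/3.72 µm for grades 1–3/4/5); the base radius of the
  outline is $r_0 = r_{\min}/(1-a)$.
* **Roughness per grade.** With this outline model the nuclear area is
  $\approx \pi r_0^2$, so requiring the generator to reproduce the
  published area row (54.01/61.16/71.14 µm²) *and* the minimal-radius row
  simultaneously fixes the roughness amplitude per grade:
  $a = 1 - r_{\min}\sqrt{\pi/A}$, giving 0.190/0.177/0.218. Pleasingly,
  this reproduces the published shape ordering — grade-4 nuclei are the
  smoothest (lowest aspect, radius ratio and contour index) while grade 5
  is the most irregular — which the raw table states independently.

Remaining knobs have no published analogue and are documented defaults
chosen once: between-sample roughness SD 0.01, vesicle rates 0.5/2/1
(bright intranuclear blobs, most frequent in grade 4 where the published
intensity rows are brightest), chromatin texture SD 15/20/16 gray levels
with a correlation length of 2 px, background 230 ± 5 (light, so nuclei
are darker than background as in haematoxylin staining). Pixel calibration
defaults to 0.25 µm/px, a typical ×400 digitisation scale at which a
3.4 µm-radius nucleus spans about 27 px; it is a parameter everywhere.

Placement uses a jittered grid, so labels can never overlap and a scene of
$n$ nuclei always fits; if a caller forces a smaller `image_size`,
sequential random placement is attempted and failure reports the achieved
count. All randomness flows from one root seed through per-scene derived
streams: identical specifications reproduce byte-identical cohorts.

What the generator deliberately does **not** model: glandular/stromal
architecture (the actual Gleason criterion), stain deconvolution physics,
optical blur, or nucleus-density gradients. Passing tests on synthetic
cohorts therefore demonstrate that the *pipeline* recovers planted
structure under the published summary statistics — not that the
discriminant would transfer to real tissue.

## The descriptor battery

`extract_geometry()` validates each label (single 8-connected component,
≥ 10 px — smaller regions are rejected, never imputed) and traces the
outer boundary with Moore neighbour tracing (Jacob's stopping criterion).

Chain-code lengths weight axial moves 0.948 and diagonal moves 1.340
(Kulpa's bias-corrected digital perimeter). The naive 1/√2 weights
overestimate the length of a smooth digitised contour by ≈ 5.5%, which
would push the contour index of a perfect disk to ≈ 1.11; with the
corrected weights a disk measures ≈ 1.0 as it should. `perimeter2` adds
the boundaries of enclosed background holes to the outer chain;
`perimeter3` is the outer chain alone; `perimeter_length` is its
semi-perimeter.

Size descriptors are computed in µm via the pixel calibration: centroid
diameters and Feret (caliper) extents on a 1° angular grid (configurable),
axis lengths from second-order central moments with the 1/12
pixel-footprint correction (an axis-aligned $w \times h$ rectangle of
pixels yields exactly the equivalent-ellipse axes of the continuous
rectangle), bounding-box sides counted as pixel extents (`max − min + 1`),
convex-hull perimeter over boundary pixel centres, and the Ramanujan
approximation for the moment-equivalent ellipse perimeter.

Shape descriptors: `roundness` is the contour index
$P_3^2 / (4\pi A)$ and `radius_ratio` the max/min centroid distance.
`fractal_dimension` is the box-counting slope of $\log N(s)$ against
$\log(1/s)$ over dyadic box sizes from 1 px up to
$\min(64, \max(\mathrm{bbox}/4, 8))$; at least four scales (bbox ≥ 8 px)
are required, otherwise the value is flagged missing. Both roundness and
the box-counting slope are clamped at their theoretical floor of 1, since
rasterization noise can push the raw estimates marginally below it.

Intensity descriptors use the unweighted RGB mean as the luminance
channel. Optical density follows the convention `OD = 256 − gray` (the
arithmetic the published chromatin table depends on — note 256, not 255),
`iod = od_mean × area` and `total_chromatin = (256 − gray_green) × area`.

The three chromatin-texture descriptors have no public reference formula;
they are fixed here by contract and tested against that contract:

* `heterogeneity` — fraction of nucleus pixels whose luminance deviates
  from the nuclear mean by more than 10% of that mean;
* `clumpiness` — fraction of those deviants surviving one pass of 3×3
  majority erosion (≥ 5 deviant pixels in the neighbourhood), i.e. the
  cluster-persistent share of the heterogeneity;
* `margination` — mean OD of the peripheral band (relative radial
  position ≥ 2/3 of the local centre-to-boundary distance) divided by
  three times the whole-nucleus mean OD, so a radially uniform nucleus
  scores exactly 1/3.

`holes` counts bright intranuclear vesicles: connected regions above
`gray_mean + gray_std` fully enclosed by the nucleus. The published
per-grade values for holes and the perimeter ratio are numerically
inconsistent with their own printed descriptions (a count of ~28, a ratio
of ~50); both are implemented as their descriptions state — a true count,
and `perimeter_convex / perimeter3 ∈ (0, 1]` — and their published
values are not treated as reference points.

## Group statistics

`aggregate_samples()` reduces nuclei to per-sample means — the unit of
analysis is the biopsy, matching a design in which grades are assigned per
sample (whether the original analysis pooled nuclei instead is not
determinable; per-sample means are the defensible default and pooling is a
one-line change). `anova_screen()` runs a classical equal-variance one-way
ANOVA per feature across the three groups; features passing the overall
test at α are followed up with pairwise two-sample comparisons using the
pooled within-group SD, Bonferroni-corrected across the three pairs (the
correction is per feature, not across the battery, mirroring the original
per-feature post-hoc column). Features with zero variance everywhere are
flagged with an undefined F rather than an error. `chromatin_summary()`
reproduces the integer chromatin arithmetic (round means, `OD = 256 −
green`, quantity = OD × area) alongside the exact unrounded product.

## Discriminant score and ROC

`paper_model()` ships the published 7-variable formula at full printed
precision (intercept 1331.50420234964; weights for minimal radius,
fractal dimension, min/max gray, margination, green and blue gray levels)
with its cutoff −1.1134. The published text never states which side of the
cutoff is high grade; evaluating the printed formula at the published
per-grade variable means gives −7.73 (grades 1–3), +9.77 (grade 4) and
+7.83 (grade 5), which fixes the orientation: higher scores mean higher
grade. Ties at the cutoff classify as high grade, favouring sensitivity
for the clinically risky class.

`fit_stepwise()` re-fits the score on new data: forward stepwise selection
for a two-class linear discriminant (low = grades 1–3, high = 4∪5) with
Wilks' lambda as the step criterion and partial-F entry/removal tests
(defaults 0.05/0.10, conventional and configurable). The original analysis
names a "Wald stepwise forward" procedure while calling the model a
discriminant analysis; Wilks-lambda stepping *is* the standard stepwise
discriminant procedure, and a logistic-regression Wald variant is provided
behind `method = "wald"` for sensitivity analysis (note that complete class
separation degenerates Wald tests, one reason it is not the default).
Returned weights are the Fisher direction scaled to unit pooled
within-class score variance, with the class midpoint at score 0.

`roc_curve()` places thresholds at midpoints between adjacent distinct
scores (±∞ included), computes AUC by the trapezoidal rule, and
`pick_cutoff()` maximises Youden's J with ties broken toward higher
specificity. The fitted pipeline replaces the provisional midpoint cutoff
with the Youden-optimal one.

## Numerical and degenerate-input choices

* Boundary tracing guards against non-termination; single-pixel and
  thin-spur chains revisit pixels by design (the chain is a closed walk).
* Wilks' lambda uses determinant ratios with a reciprocal-condition guard
  (`rcond < 1e-12` → candidate skipped), which silently absorbs exact
  duplicates of selected variables.
* The within-class covariance in the final Fisher solve falls back to a
  tiny ridge (`1e-8` of the mean diagonal) only if the plain solve fails.
* Zero-roughness boundaries are exact circles; zero-variance features are
  excluded from candidacy before stepwise search.
* All RNG consumption is wrapped so that seeded calls never disturb the
  caller's RNG stream.

## Problem sizes used in the validation suite

The packaged tests exercise: analytic fixtures (disks to radius 30 px,
rectangles, ellipses) for the descriptor oracles; 200 null-cohort
replicates of the 54-feature screen (3 × 20 samples) for the type-I error
check; 100 replicates of a 10-candidate/2-informative stepwise recovery
experiment at 30 samples per class; and one full cohort at the study scale
(24/20/16 samples × 100 nuclei) for the end-to-end grade-recovery
experiment, which checks AUC ≥ 0.95 for the low/high discrimination and
the monotone increase of mean nuclear area across grades. The same
end-to-end experiment is what `scripts/acceptance.R` reruns from a
caller-supplied seed.

## Known limitations

* Descriptor definitions for margination, clumpiness and holes are this
  package's own fixed contracts; matching the original instrument's
  per-grade numbers for those three is explicitly out of scope.
* The box-counting dimension of small (~30 px) nuclei with smooth
  harmonic boundaries sits at its floor of 1; at the default calibration
  the fractal channel contributes little grade signal, which the stepwise
  stage handles by simply not selecting it.
* The generator's realism is bounded by published summary statistics;
  performance numbers on synthetic cohorts are properties of the
  generative design, not clinical claims.
* The published 97.2%/100% sensitivity/specificity was measured on a
  private 60-biopsy cohort and is not reproducible here; the end-to-end
  synthetic experiment substitutes property-based checks.
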