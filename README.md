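# nucmorph

Computerized nuclear morphometry for prostate-cancer grading: synthetic
nucleus-image generation, a 38-descriptor morphometric feature battery,
grade-group statistics, and a 7-variable discriminant score that separates
low-grade (Gleason pattern ≤ 3) from high-grade (pattern 4–5) disease.

## Who this is for

Gleason grading is architectural and subjective; inter-observer
disagreement is a known clinical problem exactly at the decision that
matters (pattern 3 vs ≥ 4). Quantitative nuclear morphometry measures the
tumour-cell nuclei themselves — size, boundary irregularity, chromatin
density and texture — and distils them into a single discriminant score
with a fixed operating point. This package is for computational-pathology
researchers who want that pipeline as reusable, tested code: every stage
runs on synthetic cohorts with known ground truth, and every published
constant it relies on is reproduced by computation.

## The model in brief

For each segmented nucleus the package computes 38 descriptors (area,
perimeters, diameters, radii, Feret extents, moment-ellipse axes,
box-counting fractal dimension of the boundary, RGB and luminance gray
statistics, and the chromatin-texture triple margination / heterogeneity /
clumpiness). Optical density follows the convention OD = 256 − gray, and
integrated optical density IOD = OD × area proxies total chromatin
content.

Per-sample feature means are screened with one-way ANOVA across the three
grade groups (Bonferroni-corrected pairwise follow-ups), and the
multivariate stage is a linear discriminant score

    DS = 1331.50420234964
       + 5.95568628644  · radius_min      − 1479.27930311731 · fractal_dimension
       + 0.40274897061  · gray_min        + 0.53105523026    · gray_max
       + 275.38324653827 · margination    − 0.89343166330    · gray_green
       + 0.51289341737  · gray_blue

with decision cutoff −1.1134 (scores at or above the cutoff call high
grade). `fit_stepwise()` re-derives such scores on new data by forward
stepwise selection with Wilks' lambda, and `roc_curve()` /
`pick_cutoff()` choose the Youden-optimal operating point.

## Worked example

```r
library(nucmorph)

# simulate a small cohort, extract features, screen, fit, classify
run <- run_pipeline(nm_config(n_samples_per_grade = c(4, 4, 4),
                              nuclei_per_sample = 30, seed = 42))
run
#> <nm_run> 12 samples, 360 nuclei measured
#>   significant features: 9/40
#>   discriminant: fit (2 features)
#>   AUC 1.0000; cutoff -0.1419 -> sens 100.0%, spec 100.0%

# chromatin arithmetic at the published per-grade green gray levels / areas
chromatin_summary(data.frame(grade_group = c("G13", "G4", "G5"),
                             gray_green = c(97, 114, 89),
                             nuclear_area = c(54, 61, 71)))
#>   grade_group gray_green optical_density nuclear_area quantity quantity_exact
#> 1         G13         97             159           54     8586           8586
#> 2          G4        114             142           61     8662           8662
#> 3          G5         89             167           71    11857          11857

# the published formula at the published grade-1-3 variable means
ds_score(c(radius_min = 3.36, fractal_dimension = 1.058, gray_min = 85.54,
           gray_max = 178.70, margination = 0.3400, gray_green = 97.079,
           gray_blue = 135.68))
#> [1] -7.725248   # below the cutoff -1.1134: low grade, as it should be
```

The chromatin table shows the green-channel optical density (256 − gray)
and total chromatin quantity (OD × area) per grade: grade-5 nuclei are both
darker and larger, so their chromatin content jumps. The pipeline printout
reports how many features separate the groups at α = 0.05, which features
the stepwise discriminant kept, and the ROC operating point of the
resulting score on the simulated cohort.

A thin command-line wrapper is installed at `inst/cli/nucmorph.R`
(`simulate`, `run-all`, `score` subcommands).

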