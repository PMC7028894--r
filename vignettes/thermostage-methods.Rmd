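---
title: "Methods: automatic cellulite staging from infrared thermograms"
author: "thermostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic cellulite staging from infrared thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermostage)
```

## The problem

Cellulite (gynoid lipodystrophy) presents clinically in four
Nürnberger–Müller severity stages, from 0 (healthy skin) to 3 (severe,
alterations evident both standing and lying). On an infrared thermogram of
the posterior thighs, advancing cellulite shows as an increasingly
inhomogeneous surface-temperature pattern — the "orange peel" texture —
while healthy skin is thermally smooth. `thermostage` implements a fully
automatic recognition pipeline for these stages that operates purely on the
*morphology* of the false-color thermogram: no radiometric calibration and
no temperature values in kelvin are used anywhere. The intended user is a
researcher evaluating texture-based staging protocols, or anyone who needs
a reproducible, inspectable reference implementation of such a pipeline.

The pipeline has four stages, each an independent module:

1. **ROI extraction** — from a 320×240 false-color thermogram with a
   temperature bar and text overlays to a 210×240 grayscale patch of the
   posterior thighs.
2. **Feature extraction** — a fixed-length descriptor per patch; histogram
   of oriented gradients (HOG) is the reference method.
3. **One-vs-rest classification** — four binary scorers, one per stage,
   fused by best probability score; a three-layer perceptron is the
   reference family among nine.
4. **Evaluation** — stratified 70/30 splitting and per-stage
   sensitivity/specificity/precision/F-score/ROC/AUC reports.

A synthetic thermogram generator makes every stage testable without
clinical data, which cannot be redistributed.

## ROI extraction

`extract_roi()` chains, in order: grayscale conversion, annotation removal,
contrast stretch, Sobel edge detection, thresholding, noise removal, crop,
and resize. The ordering follows the natural reading of the acquisition
layout: annotations are artificial high-contrast structures and must go
before the stretch, which would otherwise be driven by the white overlay
text rather than by the thermal scene.

* **Grayscale.** RGB is collapsed with luminance weights
  (0.299, 0.587, 0.114). Rainbow palettes are *not* luminance-monotone in
  temperature; since the analysis is morphological rather than radiometric
  this is acceptable, and it is exactly the stress the synthetic generator's
  rainbow palette is designed to exercise.
* **Annotation removal.** The temperature bar (a tall strip abutting the
  left or right border) and the text strips along the top/bottom are
  detected by edge-density profiling: the widest border strip (3 px up to
  20 % of the dimension) whose mean Sobel magnitude exceeds 3× the image
  median is excised, trimmed of quiet trailing columns and padded by 2 px
  to cover anti-aliased borders. No OCR and no fixed margins, so the same
  rule works across overlay layouts.
* **Contrast stretch.** Linear percentile stretch with defaults (2, 98);
  values at or below/above the percentiles map to 0/1. A constant image is
  returned unchanged (with a warning) rather than dividing by zero. The
  stretch is monotone wherever not clipped.
* **Visible-foreground guard.** If the 2–98 percentile span of the raw
  grayscale is below 10 % of the intensity range, the image carries no
  thermal structure (an all-cold scene) and extraction fails with an
  informative error instead of amplifying noise into a spurious crop.
* **Edges and threshold.** Standard 3×3 Sobel kernels with reflected
  borders; the magnitude is thresholded by Otsu's method by default
  (`edge_threshold` overrides). Components smaller than 64 px are removed,
  then a 3×3 morphological closing merges fragmented outlines.
* **Crop rule.** All components of at least half the largest component's
  area count as thighs; their union bounding box is cropped. This covers
  both the two-separate-thighs and the merged-after-closing cases. A
  bounding box under 16 px a side is rejected as degenerate.
* **Resize.** Bilinear, with anti-aliasing, to 210×240; output clamped to
  [0, 1].

On synthetic datasets with the clinical class distribution (212 images)
extraction succeeds on 100 % of images across seeds, mirroring the behavior
the protocol requires of its preprocessing.

## Feature extraction

**HOG** (`hog_features`) is the reference descriptor. Gradients are
centered differences; orientations are folded to [0°, 180°); each pixel
votes its magnitude into per-cell orientation histograms with linear
interpolation between the two nearest of 9 bin centers (wrap-around);
2×2-cell blocks at stride 1 are L2-normalized independently and
concatenated row-major. With the default 48-px cells on a 210×240 patch:
floor(210/48) = 4 cell rows, floor(240/48) = 5 cell columns, hence 3×4
blocks × 4 cells × 9 bins = **432 features**. This block structure is the
unique standard configuration consistent with both the 48-px cell size and
the 432-dimensional total; the flattened patch itself has 50,400 raw
pixels. The dimensionality formula is property-tested against brute-force
cell/block counting.

Five simpler extractors share the same interface: `stat` (8 fixed-order
intensity summaries: mean, variance, skewness, kurtosis, median, 10th/90th
percentiles, 64-bin histogram entropy in bits), `cont` (perimeter, area,
compactness, eccentricity, solidity of the largest Otsu component), `lbp`
(rotation-invariant uniform local binary patterns, 8 neighbors at radius 1,
10-bin normalized histogram), `pca` (projections onto a train-only basis,
default k = 40 capped at n−1), and `eucdist` (Euclidean distances to the
four per-stage mean images). Keypoint descriptors (SURF, BRISK and their
combinations) are out of scope: their aggregation into fixed-length vectors
is not specified by any published configuration of this protocol.

Two numerical choices deserve a note. The contour perimeter is measured as
the length of the 0.5-level contour of the Gaussian-smoothed (σ = 1.2)
component mask: raw boundary-pixel counting misestimates curved boundaries
by >20 %, while the smoothed contour tracks both a 50×100 rectangle (to
1.4 %) and discs (isoperimetric ratio to 0.6 %). And stateful extractors
(PCA, templates) can only be fitted through `fit_extractor()` on an
explicit training list — the interface itself prevents test-set leakage.

## One-vs-rest classification

For each stage *s* a binary scorer is trained on labels *y* = 1 iff
stage = *s*; at prediction time the stage with the best probability score
wins, ties toward the lower stage. Features are z-scaled with training-set
statistics. Because the clinical class prevalences are unbalanced (93
stage-1 images versus 27 stage-0), each binary fit weights samples by
inverse prevalence by default (`balance_weights = FALSE` disables;
MinDist, KNN and NB have no weighted form and ignore the toggle).

Nine families are available. The reference **ANN** is a three-layer
perceptron written in the package: one hidden layer (default 20 sigmoid
units), a single sigmoid output, weights initialized uniformly in
[−0.5, 0.5] from a seed, full-batch gradient descent (default rate 0.05,
500 epochs) on sample-weighted binary cross-entropy, with the per-epoch
loss recorded. The hidden width keeps the parameter count (~8.7k with
432-dim input) modest relative to 149 training images. The other families
delegate to the standard implementations (`e1071`, `MASS`, `class`,
`rpart`, `randomForest`, `glmnet`) behind a uniform score transform:
native posteriors where they exist, Platt-style calibrated decision values
for the SVM, neighbor fractions for KNN, leaf fractions for trees, and a
scale-free softmin over centroid distances for MinDist. **LogReg** is
ridge-penalized logistic regression (α = 0, small fixed λ): with p = 432
features and n = 149 images the unpenalized likelihood is non-identifiable,
and a small ridge is the minimal standard remedy. No hyperparameter search
is performed anywhere; all defaults are fixed and documented
(`default_run_config()` prints every one).

## Evaluation protocol

`stratified_split()` assigns `round_half_up(0.7 n)` images of each stage to
training — for class counts {27, 93, 61, 31} exactly {19, 65, 43, 22} train
and {8, 28, 18, 9} test, 149/63 in total. Within-stage assignment is a
seeded permutation: stratification is what guarantees every stage is
represented, and the seed makes the necessary within-stage ordering
reproducible. `balanced = TRUE` first subsamples every stage to the
minimum per-stage count, reproducing a balanced-database design.

`evaluate_model()` reports, per stage: TPR, FNR, TNR, FPR, PPV, F-score,
AUC and the one-vs-rest **class accuracy** (tp+tn)/N — the definition
consistent with every published per-stage value of this protocol — plus
unweighted averages over the stages present. ROC curves place one
operating point per distinct score threshold plus both endpoints; with
all-tied scores the curve is exactly the chance diagonal. AUC is
trapezoidal, which equals the Mann–Whitney pair-counting statistic with
ties counted one half; the test suite verifies this identity on hundreds
of random instances and against `pROC`.

Reported metrics are printed to 3 decimals (round-half-even). Published
tables of this protocol mix rounding with truncation, so internal
consistency is asserted with an absolute tolerance of 10⁻³.

## The synthetic generator

`generate_thermogram()` builds a pseudo-temperature field — cool background
(0.15), two warm elliptical thighs (plateau +0.4 with a soft rim and small
geometric jitter), Poisson-many Gaussian mottling blobs inside the thigh
masks, i.i.d. Gaussian pixel noise — maps it through a rainbow (jet-like)
or grayscale palette, and composites a temperature bar (palette ramp, tick
marks every 12 px with speckled tick labels, dark border) and speckled text
strips. The ground-truth thigh mask rides along as an attribute so ROI
recall is measurable; everything is bit-reproducible from (stage, seed).

Mottling is the severity knob: per-stage blob count λ = (0, 6, 14, 26) and
amplitude a = (0, 0.08, 0.14, 0.22) of the dynamic range, both necessarily
zero for healthy skin and non-decreasing in stage — the simplest monotone
encoding of "increasingly inhomogeneous". Blob radii span 4–10 px. The
noise level defaults to 0.01 of the range: a clinical camera with ~50 mK
thermal sensitivity displaying a span of a few kelvin has a noise floor
near 1 % of the displayed range. The rainbow palette is deliberately
luminance-non-monotone to stress the grayscale conversion.

What the generator does *not* emulate: physically realistic heat transfer,
anatomically accurate thigh shapes, pose variation, vignetting, or FLIR's
radiometric encoding. Passing tests on synthetic data therefore demonstrate
that the pipeline's machinery is correct and that it recovers known
texture differences; they are **not** evidence about clinical
discriminability of real cellulite stages, for which the original study's
images would be required. No ground-truth mapping from clinical stage to
thermal texture statistics exists; the synthetic effect sizes are test
instruments, not clinical claims.

## Problem sizes and observed behavior

The shipped tests run the complete protocol on synthetic studies of 212
images with the clinical class distribution {27, 93, 61, 31}. At the
default effect sizes, HOG+ANN multiclass accuracy lands around 0.57–0.68
across split seeds — clearly above the 28/63 ≈ 0.444 majority rate — with
stage-averaged class accuracy near 0.79. With all stage effects zeroed the
classes are exchangeable by construction and accuracy returns to within
three binomial standard errors of the majority rate; this two-sided bracket
is the core sanity check that the learner finds texture, and only texture.

Under a large-effect setting (λ = 0/15/60/200, a = 0/0.2/0.45/0.8, radii
3–8 px, ANN rate 0.3) the stage-averaged class accuracy exceeds 0.9 on
every tested seed. A known representational limitation caps the multiclass
top-1 accuracy near 0.85 there: HOG's per-block L2 normalization discards
gradient magnitude, and its cell histograms saturate once blob density
approaches one blob per cell, so very severe textures become mutually
similar. A random forest on the same HOG features reaches only ~0.9, while
amplitude-sensitive features (statistical moments, LBP) separate the same
images almost perfectly — the ceiling belongs to the descriptor, not the
classifier.

## Design choices made where the design was open

* Filename labels use the token `_stageK` (K ∈ 0..3) in the basename;
  manifest labels always override filename labels. The original clinical
  coding scheme is unpublished, so this is an artifact convention, chosen
  to be explicit and greppable.
* JPEG input is accepted with a warning: lossy compression perturbs exactly
  the gradient structure HOG measures, but field data is often JPEG.
* Images are stored row-major, origin top-left; coordinates are 1-based in
  R with closed integer ranges, and all crops are explicit row/column
  ranges — one fixed convention to prevent off-by-one crop bugs.
* How the simpler extractors were originally scaled for classifier input is
  unspecified; here every extractor stands alone and per-feature z-scaling
  lives inside the classifier harness instead.
* The average row of the metrics report is the unweighted mean over stages.
  A published average AUC of this protocol (0.77406) differs from the
  unweighted mean of its own four per-stage AUCs (0.7735); the package
  reports the unweighted mean and makes no attempt to match the former.
* Model files are versioned RDS blobs with the feature configuration and
  scaling parameters embedded; the format is documented but not guaranteed
  stable across versions.

## Command-line interface

The installed package ships a `thermostage` executable (`exec/`), a thin
wrapper over `run_pipeline()` with commands `simulate`, `preprocess`,
`extract`, `train`, `evaluate`, and `benchmark`. Configuration comes from a
flat YAML file (`--config`), overridden by flags (`--seed`,
`--log-level`); `--show-config` prints the effective configuration, and
unknown keys are rejected by name. Every run writes a JSON run record
(package and R versions, seed, full configuration and its hash, input
hashes, output paths) sufficient to reproduce its outputs exactly.
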