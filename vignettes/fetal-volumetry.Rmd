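---
title: "Automatic fetal volumetry: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic fetal volumetry: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalvol)
```

## The problem

Fetal weight is a central quantity in prenatal care: it drives growth
assessment and it is the denominator when fetal blood flow is indexed for
physiological comparison across fetuses. 3D MRI of the gravid uterus allows
fetal volume to be measured directly, and weight follows from a tissue
density of 1.04 g/ml, but manual voxel-wise delineation of a fetus takes on
the order of hours per case. `fetalvol` implements an automatic pipeline:

1. the 3D slab is resampled to an isotropic working grid;
2. a small 2D U-net classifies every pixel of every slice as background,
   fetus, placenta, umbilical cord, or amniotic fluid, separately along the
   three orthogonal slicing directions (a "2.5D" or tri-planar scheme);
3. the three per-voxel predictions are fused by majority voting;
4. the fetal volume, weight (volume x 1.04), Hadlock biometry weights,
   Bland-Altman agreement statistics, and weight-indexed blood flow are
   computed from the fused segmentation.

No patient data ship with the package. Instead a synthetic gravid-uterus
phantom generator provides volumes with analytic ground truth, so every
stage of the pipeline is testable end to end.

## The label model

Four intrauterine structures are delineated: fetus, placenta, umbilical
cord, and amniotic fluid. The package adds an explicit fifth class,
background (index 0), for maternal tissue outside those structures: a
per-pixel softmax classifier needs an "everything else" category because
the acquired slab covers the whole uterus and its surroundings. Class
indices are fixed (`fetal_classes()`): 0 background, 1 fetus, 2 placenta,
3 umbilical cord, 4 amniotic fluid.

## The synthetic phantom

### Geometry

The phantom emulates a gravid uterus as a set of axis-aligned solids
(all sizes in mm):

* **uterus** — an ellipsoid filling most of the grid; its interior is
  amniotic fluid;
* **placenta** — a spherical-shell sector on the uterine wall: in
  normalized coordinates `q = (p - centre) / semi_axes`, the region
  `0.8 <= |q| <= 1` within a 55 degree cone around +y;
* **fetus** — a trunk ellipsoid, a head ellipsoid overlapping it coaxially
  (their axial cross-sections have equal aspect ratio so the overlap is a
  clean lens), two arm cylinders along x, and two leg cylinders along z,
  one of which is the femur segment whose length defines FL;
* **umbilical cord** — a tube of radius 2.5 mm along a quadratic Bezier
  curve from the trunk surface to the inner placental surface.

The default grid is 48 x 56 x 40 voxels at the acquired-resolution spacing
of 1.8 x 1.4 x 2.5 mm, i.e. a deliberately miniaturized uterus of about
86 x 78 x 100 mm. This is the package's own choice of problem size: it keeps
a full 28-case cohort, CPU training, and tri-planar inference comfortably
inside desk-scale budgets while exercising exactly the same code paths as a
full-size slab would. The consequence is that absolute phantom fetal
volumes (~14 ml at scale 1) are far below clinical fetal volumes, so
comparisons between Hadlock weights and density-based weights on phantoms
are meaningful as rank/agreement checks, not as absolute clinical values.
`fetal_scale` scales all fetal solids isotropically (default cohort spread
0.85-1.25) to emulate a span of fetal sizes.

### Ground truth

Per-class truth volumes are computed from the geometry, not from voxel
counts: closed forms for the ellipsoids, cylinders, and the shell sector,
minus pairwise overlap corrections (head-trunk, limb-trunk) evaluated by
deterministic fine midpoint-grid integration over the overlap bounding box
(relative error around 1e-4 on corrections that are themselves only a few
percent of the fetal volume). The cord volume is `pi r^2 L` with the arc
length obtained by adaptive quadrature; its end caps are a sub-percent
approximation and no test asserts cord truth to tight tolerance. Voxelized
fetal volumes agree with the truth to well under 3% at the default spacing
and converge as the grid is refined — that convergence is asserted by the
test suite.

Analytic biometry stands in for manual caliper measurements: BPD is the
head's minor axial diameter, HC and AC are Ramanujan ellipse-perimeter
approximations of the head and trunk axial cross-sections, and FL is the
femur segment length.

### Intensities and noise

Class intensities are fixed constants in bright-fluid (bSSFP-like) order:
fluid 1.0, fetus 0.55, cord 0.5, placenta 0.4, background 0.2. On top of
the piecewise-constant image the generator applies a smooth multiplicative
bias field (product of seeded random-phase cosines, amplitude
`bias_field_amp`, default 0.05, i.e. +/-5% coil-type shading) and additive
Gaussian noise (`noise_sigma`, default 0.02, an SNR of roughly 25 for fetal
tissue). The defaults are mild but deliberately place the cord (0.5) and
fetus (0.55) intensities within a couple of noise standard deviations of
each other, so the network must use spatial context rather than thresholds.
Noise is Gaussian rather than Rician: magnitude-MRI noise realism is not
needed to test the pipeline's contracts. What the phantoms do **not**
emulate — fetal motion, articulated pose, partial-volume fat/fluid
interfaces, B0/banding artifacts — is exactly what a passing phantom suite
cannot certify on clinical data.

## The network

The segmentation model is a small 2D U-net implemented inside the package
(Rcpp/Armadillo): im2col 3x3 convolutions, ReLU, 2x2 max pooling, nearest-
neighbour upsampling with skip concatenation, a 1x1 output convolution, and
a per-pixel softmax. Default depth 3 and 8 base channels (~26k parameters)
is the smallest configuration that segments the phantoms well on one CPU.
Training uses weighted cross-entropy with Adam (default 3e-3, batch of 4
slices, 12 epochs, 24 random slices per volume per epoch pooled across all
three axes). Backpropagation is verified against finite differences in the
test suite. All stochastic elements (initialization, slice sampling,
augmentation) run off a single seed, and training is single-threaded
deterministic.

Design choices worth recording:

* **One shared net, three directions.** The tri-planar scheme could use
  three axis-specific models; the package trains a single net on slices
  from all axes. On near-isotropic working grids the slice statistics are
  similar across axes, the shared model sees 3x more data, and one model is
  simpler to manage.
* **Class weights.** The cross-entropy weights default to upweighting only
  the thin umbilical cord, which would otherwise be ignored entirely.
  Upweighting the *fetus* class was rejected: in boundary pixels a weighted
  loss shifts the decision boundary outward and inflates the segmented
  fetal volume by several percent — a systematic volumetric bias — while
  barely changing Dice.
* **Slices with no foreground are kept** in training; background prevalence
  is informative.
* **Input sizing.** Slices are zero-padded to the next multiple of
  `2^(depth-1)` and the output cropped back; no shape is ever rejected.

## Vote fusion

Each direction casts one hard vote per voxel — its argmax class — and a
majority (at least two votes) wins. When all three directions disagree, the
tie is broken by the largest sum of the three directions' probabilities
over the tied classes, and any residual tie by the lowest class index, so
fusion is a pure, deterministic function. The test suite checks the
implementation against a brute-force enumeration of all 5^3 vote patterns
and verifies that unanimity is always preserved. Soft fusion (averaging
probabilities before the argmax) was considered and not made the default:
hard voting is the literal reading of per-direction voting, and the
probability sum already arbitrates the only ambiguous case.

## Resampling

The acquired grid is anisotropic (1.8 x 1.4 x 2.5 mm) but tri-planar
slicing treats the axes symmetrically, so volumes are resampled to an
isotropic working grid before inference — default 1.5 mm, near the finest
acquired in-plane resolution. Intensities are interpolated trilinearly;
label maps always use nearest-neighbour, which preserves the label
alphabet. Grids are cell-centred and only axis-aligned geometries are
supported (phantoms are axis-aligned; oblique affines are out of scope).
The fused segmentation is mapped back to the native grid by nearest-
neighbour lookup, and Dice against ground truth is always evaluated on the
native grid of the truth, so that evaluation does not reward resampling
artifacts. An optional postprocessing step keeps only the largest
26-connected component of the fetus class; stray fetal islands become
background.

## Quantification conventions

* Volume: voxel count x voxel volume; weight = 1.04 g/ml x volume.
* Dice `2|A n B|/(|A|+|B|)`; two empty sets give 1 (perfect agreement on
  absence — the raw formula is 0/0).
* Hadlock formulas 1-4 take cm and return grams (`10^L`); any other unit
  reading yields absurd magnitudes. Inputs outside the physiological
  ranges (AC 15-45, FL 2-9, HC 15-40, BPD 4-12 cm) warn but still compute,
  since the formulas' reduced reliability at the extremes is a documented
  property, not an input error.
* Bland-Altman: bias = mean difference, SD with n-1, limits of agreement
  bias +/- 1.96 SD (large-sample form, no t correction), percent
  differences use the per-pair mean as denominator; a zero pairwise mean
  makes the percent statistics undefined (`NA`) while absolute statistics
  remain.
* Flow: `sum_roi(v * pixel_area) * 0.01` ml/s per phase, all phases
  weighted equally (retrospective cine convention), times 60 for ml/min;
  signed velocities so reversed flow subtracts. Pixels are in or out of
  the ROI — no partial-pixel weighting, matching manual delineation
  practice. No phase unwrapping or background-phase correction is applied;
  velocities beyond the VENC are rejected at generation instead.
* Indexed flow = flow / weight in kg.

## The end-to-end validation and its scale

The acceptance-level test generates a fixed 28-phantom cohort (seeded),
trains the default network on 20 cases, and evaluates on the 8 held-out
cases, requiring mean fetal Dice >= 0.85 and per-case absolute volume error
<= 10%. These bounds are the package's desk-scale analog of the clinical
validation regime and are deliberately looser than what the phantoms
typically achieve (mean fetal Dice around 0.93-0.95). The fold harness (`make_folds`) reproduces
the 20-case, fourfold, 15-train/5-validation arithmetic and is used by the
demonstration pipeline (`run_demo`), which trains one model per fold and
selects the best fold by final validation loss.

## Known limitations

* Phantom realism is intentionally limited (see above); clinical
  performance claims cannot be made from phantom results.
* Only axis-aligned NIfTI geometries are supported; DICOM ingestion,
  oblique affines, and 4D acquisitions are out of scope.
* The cord class is hard for the default network at coarse resolution; the
  pipeline's figure of merit is the fetus.
* Hadlock estimates on miniature phantoms sit far outside the formulas'
  calibration range and are exercised for ranking/agreement behaviour only.
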