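# fetalvol

Automatic fetal volumetry from 3D MRI: tri-planar 2D U-net segmentation
with voxel-wise vote fusion, density-based fetal weight, Hadlock biometry
formulas, Bland-Altman agreement analysis, and weight-indexed blood-flow
quantification — fully testable on synthetic gravid-uterus phantoms with
analytic ground truth.

## Who this is for

Quantifying fetal volume from a 3D MRI slab normally requires manual
voxel-wise delineation (hours per case). This package implements an
automatic pipeline for researchers working on fetal MRI volumetry and flow
physiology:

* a small 2D U-net (implemented in-package with Rcpp/Armadillo) classifies
  every pixel of every slice as background, fetus, placenta, umbilical
  cord, or amniotic fluid;
* the net runs along all three orthogonal slicing directions of the
  isotropically resampled volume, and the final label of each voxel is a
  **majority vote of the three directions** — ties broken by the summed
  class probabilities, then by lowest class index;
* fetal weight follows from the segmented volume as
  `weight [g] = 1.04 [g/ml] x volume [ml]`;
* Hadlock's ultrasound biometry formulas 1-4 (inputs in cm, output grams),
  e.g. formula 1:
  `log10(W) = 1.304 + 0.05281 AC + 0.1938 FL - 0.004 AC x FL`,
  allow weight estimation when only biometry is available;
* blood flow is integrated over a vessel ROI from phase-contrast velocity
  maps (`sum(v x pixel_area)`, cycle-averaged, ml/min) and indexed to
  fetal weight (ml/min/kg);
* agreement between any two methods is summarized Bland-Altman style:
  bias, SD of differences (n-1), and 95% limits of agreement
  `bias +/- 1.96 SD`, absolute and percent.

No patient data are included. A synthetic phantom generator produces
gravid-uterus volumes (fetus with head/trunk/limbs, placenta, cord,
amniotic fluid), with closed-form ground-truth volumes, analytic biometry,
and Poiseuille flow phantoms, so the whole pipeline validates end to end
on data built at test time. See `vignettes/fetal-volumetry.Rmd` for the
methods and design choices.

## Worked example

```r
library(fetalvol)

# a deterministic synthetic cohort: 8 training cases, 1 test case
cohort  <- generate_cohort(9, seed = 7)
dataset <- lapply(cohort[1:8], function(p)
  list(volume = p$volume, labels = p$labels))
model <- train_unet(net_config(seed = 7), dataset)

ph  <- cohort[[9]]
seg <- segment_volume(model, ph$volume)

dice(seg, ph$labels, class_index = 1L)        # fetal Dice vs ground truth
label_volume_ml(seg, 1L)                      # automatic fetal volume (ml)
ph$truth$volumes_ml[["fetus"]]                # analytic truth (ml)
weight_from_volume(label_volume_ml(seg, 1L))  # density-based weight

hadlock_weight(1, biometry_set(AC = 32, FL = 6.5))

f <- generate_flow_phantom(radius_mm = 4, v_max_cm_s = 20, n_phases = 1)
flow_ml_per_min(f, weight = weight_from_volume(2500))
```

Output from this exact script:

```
[1] 0.9485681
[1] 10.6218
[1] 10.78097
weight_estimate: 11.0 g (mri_volume)
weight_estimate: 2640.1 g (hadlock_1)
flow_result: 299.4 ml/min (115.2 ml/min/kg)
```

Reading the numbers: the automatic fetal volume agrees with the analytic
truth to a few percent and fetal Dice is around 0.93-0.95 on phantoms; the Hadlock
weight is what a clinician would estimate from an AC of 32 cm and FL of
6.5 cm; the flow phantom's integrated flow sits within a percent of the
closed-form Poiseuille value `v_max pi R^2 / 2 = 301.6 ml/min`, and
indexing divides by weight in kg.

A command-line front end with subcommands
(`phantom | train | segment | quantify | hadlock | flow | agree | demo`)
is installed at `inst/cli/fetalvol.R`; `demo` runs the full pipeline
(cohort, fourfold cross-validation, test-set segmentation, agreement and
flow reports) into an output directory.

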