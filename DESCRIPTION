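Package: fetalvol
Title: Automatic Fetal Volumetry from 3D MRI by Tri-Planar 2D U-Net
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic quantification of fetal volume and weight from 3D
    magnetic resonance images. A small 2D U-net convolutional network is
    applied slice-by-slice along the three orthogonal directions of an
    isotropically resampled volume and the three per-voxel predictions are
    fused by majority voting. Fetal weight is derived from the segmented
    volume using a fetal density of 1.04 kg/l and compared with Hadlock's
    ultrasound biometry formulas 1-4. Phase-contrast blood-flow series are
    integrated over a vessel region of interest and indexed to fetal weight.
    Agreement between methods is summarized with Bland-Altman statistics.
    A synthetic gravid-uterus phantom generator with analytic ground-truth
    volumes, biometry, and Poiseuille flow makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
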