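Package: ctsr
Title: Slice-Thickness Super-Resolution and Lung Nodule Volumetry for Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for normalizing heterogeneous CT slice thickness by 3D
    super-resolution and for the downstream volumetric assessment of lung
    nodules. Implements an ESRGAN-style 3D generator built from
    residual-in-residual dense blocks with a voxel-shuffle slice-generation
    head that multiplies the slice count along the stack axis, an adversarial
    discriminator, the associated pixel, perceptual and adversarial losses,
    and a self-supervised training loop in which thin-slice volumes are
    degraded by consecutive-slice averaging to form training pairs. Includes a
    seeded synthetic chest phantom generator with nodules of known analytic
    volume, voxel-count nodule volumetry with Hounsfield-threshold nodule
    typing, repeatability statistics, and simplified volume-based Lung-RADS
    v2022 categorization with confusion-matrix agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
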