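Package: tbiq
Title: Quantification of Acute Traumatic Brain Injury Features on Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of acute traumatic brain injury on
    non-contrast head CT: acute intracranial lesion segmentation with a
    patch-based 3D U-Net and two-stage hard-negative retraining, basal
    cistern segmentation from atlas priors and constrained morphology,
    expectation-maximization tissue segmentation, affine atlas registration,
    and geometric midline-shift estimation.  Includes a synthetic head-CT
    phantom generator with exact ground truth for validation, and the full
    agreement-metric suite (Dice, precision, sensitivity, volume differences,
    absolute-agreement ICC, cutoff classification accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
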