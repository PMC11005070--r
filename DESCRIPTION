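Package: kcscreen
Title: Automated Keratoconus Screening from Corneal Tomography Indexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes nineteen curvature, elevation and thickness screening
    indexes from anterior-segment corneal tomography maps (anterior and
    posterior elevation; corneal, epithelial and stromal pachymetry),
    including symmetry and center-surrounding curvature indexes, Zernike
    based ectatic indexes, deviation from best-fit aspho-toric reference
    surfaces, percentage thickness-increase profiles and the spread of the
    notable points. A multilayer perceptron trained by backpropagation
    assigns one of five diagnostic classes (normal, keratoconus, keratoconus
    suspect, myopic post-operative, abnormal). Includes per-index ROC/AUC
    analysis with Hosmer discrimination grading, percentile normality
    ranges, confusion-matrix metrics, and a synthetic corneal phenotype
    simulator so the whole screening pipeline can be exercised and tested
    without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
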