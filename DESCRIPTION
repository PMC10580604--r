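Package: wsiSurv
Title: Tissue-Area and Deep Cox Features for Whole-Slide Image Survival
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based survival prediction from whole-slide histopathology
    tissue maps. Provides a synthetic cohort generator with known ground
    truth, patch sampling and nine-class tissue classification, binary grid
    morphology (closing with a rectangular structuring element, connected
    component labeling, hole filling), the five tissue-area features
    (maximal tumor area, lymphocytes inside and around tumors, their
    smoothed ratio, total stroma area), a convolutional Cox partial
    likelihood feature extractor producing per-tissue 32-dimensional
    histopathological features, maximally selected rank statistic cutpoints
    with permutation p-values, Kaplan-Meier and log-rank utilities, six
    survival models evaluated by cross-validated concordance index, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    nnet,
    glmnet,
    ranger,
    xgboost,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
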