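Package: drugresp
Title: Cell-Line-Derived Drug-Sensitivity Signatures via Ensemble PLSR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds drug-sensitivity predictive models from cancer cell-line
    panels and translates them to patient cohorts profiled on a different
    expression platform. Starting from a log2 expression matrix and per-cell-line
    IC50 values, the pipeline performs dose-response quality control, intensity
    and variance data reduction, permutation-based feature selection on
    Fisher-transformed correlations, an ensemble of balanced/random splits
    driving partial least squares regression (PLSR) model selection, consensus
    gene weighting by singular value decomposition with forward selection to a
    core signature, pathway-based signature filtering, and clinical evaluation
    of the final model by response classification and progression-free-survival
    stratification. A synthetic-data module generates panels, dose-response
    curves and clinical cohorts with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    optparse
Config/testthat/edition: 3
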