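Package: perisk
Title: Preeclampsia Risk Prediction with Bi-Platform PlGF Calibration
Version: 0.1.0
Authors@R:
    person("perisk", "developers", email = "perisk@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for preeclampsia (PE) risk
    prediction from routine clinical variables and placental growth factor
    (PlGF) measured on either the SiMoA or Elecsys immunoassay platform.
    Provides a synthetic clinical cohort generator with controlled missingness
    and known cross-platform transfer; encoding of 14 collected variables into
    a 22-feature design matrix; dual-strategy missing-data imputation
    (class-conditional medians plus relation-network imputation for dependent
    feature pairs); cross-platform PlGF calibration by median-model selection
    over repeated 3-fold cross-validation of small sigmoidal networks;
    imbalance-aware classifier training with output-threshold optimisation;
    repeated and modified cross-validation protocols including an
    early-pregnancy enrichment scheme; and interpolation-based minority
    oversampling with a leakage-aware evaluation of the virtually-high
    performance phenomenon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
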