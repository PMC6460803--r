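Package: ordcombo
Title: Biomarker Combinations for Single-Level Prediction of an Ordinal Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Constructs biomarker combinations for predicting the top level of
    an ordinal outcome using seven regression strategies (dichotomized binary
    logistic, sequential binary logistic, cumulative logit, adjacent-category
    logit, continuation-ratio logit, one-dimensional stereotype, and
    baseline-category logit), and selects among candidate combinations with a
    rank-sum algorithm that uses AUCs at multiple outcome levels together with
    bootstrap correction for resubstitution bias. Includes conditional-Gaussian
    and cumulative-logit data generators and a Monte Carlo driver for
    simulation studies of combination construction and selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    nnet,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
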