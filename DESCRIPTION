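Package: dcftmle
Title: Generalized Double Cross-Fitted TMLE for Average Treatment Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Targeted maximum likelihood estimation (TMLE) of the average
    treatment effect (risk difference) of a binary treatment on a binary
    outcome, with generalized double cross-fitting: the propensity model,
    the outcome model and the effect estimate each use mutually disjoint
    data splits, for an arbitrary number of splits p and repetitions r.
    Two split-role schemes are provided (equal single-split roles, and a
    full-data scheme that divides the non-estimation splits equally
    between the two nuisance models), together with a cross-validated
    super learner for nuisance estimation, a non-cross-fit TMLE
    comparator, synthetic data generators with known truth, and a Monte
    Carlo harness computing bias, empirical and model-based standard
    errors, coverage and related performance measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    nnet,
    randomForest,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
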