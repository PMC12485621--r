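Package: ystrancestry
Title: Y-STR Haplotype Ancestry Classification with Calibrated Ensembles and Attention Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for inferring the population of origin of male DNA samples
    from Y-chromosomal short tandem repeat (Y-STR) haplotypes. Implements a
    one-vs-rest ensemble of per-population binary classifiers (regularized
    logistic regression, random forests, gradient-boosted trees) with Platt
    probability calibration, attention-weighted fusion of the calibrated
    expert probabilities, and a fully connected meta-network producing final
    class probabilities; a one-vs-one stacking architecture is provided as a
    comparator, together with its pairwise-accuracy matrix. Includes a
    haplotype table data model with microvariant-aware allele handling, a
    synthetic Y-STR population simulator with Dirichlet allele frequencies
    and controllable admixture, mutual-information feature selection, a
    sequential model-based hyperparameter tuner, and a full evaluation suite
    (per-class reports, confusion matrices, misclassification summaries,
    discriminative-allele rankings, calibration diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lhs,
    ranger,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
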