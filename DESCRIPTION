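Package: cpmiq
Title: Connectome-Based Predictive Modeling of Intellectual Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Transdiagnostic connectome-based prediction of Full-Scale
    Intelligence Quotient (FSIQ) from resting-state functional connectivity.
    Implements edge screening by Pearson correlation, LASSO regression with
    nested run-grouped cross-validation, unified-model construction by
    cross-fold weight averaging, label-permutation inference (within-cohort
    and for transfer to external cohorts), ROI- and network-level importance
    decompositions with leave-one-network-out lesioning, IQ-subdomain
    multiple regression with controlled edge-resampling nulls, and an
    individual-differentiability statistic. Ships a synthetic-cohort
    generator with a planted sparse edge-trait structure so the full
    pipeline is testable without access-restricted clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
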