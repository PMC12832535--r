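Package: lungstrain
Title: Respiratory 4D-CT Lung Strain Analysis and Diagnostic Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biomechanical analysis of respiration-resolved (4D) thoracic CT.
    Provides threshold-and-morphology lung segmentation, centroid plus
    mutual-information translational alignment of respiratory phases with
    target-registration-error gating, dense Farneback optical-flow
    displacement fields, strain-tensor eigendecomposition with per-patient
    principal-strain and displacement-velocity summaries (PSmax, PSmean,
    Speedmax), end-inspiration CT densitometry (LAA%, mean lung density,
    15th-percentile density), and the accompanying diagnostic-statistics
    stack: normality-routed two-group tests, Cohen's d, Spearman correlation,
    ROC analysis with Youden cutoffs and DeLong inference, bootstrap optimism
    correction with BCa intervals, multivariable logistic regression,
    caliper-constrained propensity matching, and post-hoc power. Deformable
    digital lung phantoms with analytically known displacement and strain,
    and a cohort simulator with calibrated rank-correlation structure, make
    every stage verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    oro.nifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
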