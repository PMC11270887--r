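Package: informiss
Title: Missing-Data Strategies for Longitudinal Clinical Prediction Under
    Informative Missingness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Benchmarks strategies for handling informatively missing
    (not-missing-at-random) laboratory data when building longitudinal
    clinical prediction models, using inpatient deterioration over 12-hour
    blocks as the exemplar task. Provides a synthetic electronic-health-record
    cohort generator with a latent severity process and configurable
    MCAR/MAR/NMAR observation mechanisms; mean, predictive-mean-matching,
    normal-value and categorical-encoding imputation with optional
    last-observation-carried-forward; a learnable missingness-embedding
    encoder with conditional scaling; L1-penalised logistic regression,
    multilayer-perceptron and LSTM classifiers with a successive-halving
    tuner; and an evaluation stack of length-of-stay-stratified weighted
    AUROC, patient-level bootstrap confidence intervals, relative-risk
    missingness diagnostics and standardised mean differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
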