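Package: pathsig
Title: Path-Signature Features for Longitudinal Brain-Volume Trajectories
Version: 0.1.0
Authors@R:
    person("pathsig", "developers", email = "pathsig@example.org",
           role = c("aut", "cre"))
Description: Computes truncated path signatures and log signatures of
    irregularly sampled multivariate trajectories, and uses them as
    fixed-length features for predicting conversion to Alzheimer's
    disease from longitudinal MRI volume measurements (whole brain,
    hippocampus, ventricles).  Includes cohort selection with
    trajectory-based labelling and age matching, L1-penalised logistic
    regression with 10-fold cross-validated deviance and the
    one-standard-error rule, ROC-based thresholding and confusion-matrix
    evaluation, and a synthetic longitudinal cohort generator so the
    full pipeline runs without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
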