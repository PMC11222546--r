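Package: ecglyte
Title: ECG-Based Electrolyte Concentration Regression with Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and modelling pipeline for predicting
    continuous blood electrolyte concentrations (potassium, calcium, sodium,
    creatinine) from multi-lead ECG waveforms. Provides a controllable synthetic
    ECG cohort generator with a known electrolyte-to-morphology forward model,
    clinical-style dataset construction (ECG/lab linking within a time window,
    median target assignment, patient-level random and temporal splits), a small
    1-D convolutional residual network with direct, heteroscedastic Gaussian,
    classification and rank-consistent ordinal regression heads, classical
    baselines (PCA features with linear/boosting/forest regressors, batch-wise
    linear and MLP models), ensemble and last-layer Laplace uncertainty
    estimation, and an evaluation suite covering regression metrics, cumulative
    ROC analysis of discretized targets, sparsification, calibration and
    distribution-shift protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
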