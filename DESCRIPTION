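Package: glucostack
Title: Adaptive Weighted Stacking Ensembles for Continuous Glucose Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-horizon blood-glucose forecasting from continuous glucose
    monitoring (CGM) traces with a stacking ensemble of recurrent neural
    networks. Provides CGM preprocessing (gap filling, scalar Kalman
    filtering, Holt double exponential smoothing, min-max normalization),
    sliding-window supervised framing over multiple history windows, three
    LSTM-family base learners (bidirectional, stacked, and peephole cells)
    trained with Adam and early stopping, adaptive base-model weighting via
    affinity-propagation clustering on a variance-penalized similarity,
    a linear stacking meta-learner fit on out-of-fold predictions, and
    clinical evaluation (RMSE, MAE, glycemic-band Matthews correlation,
    Clarke error-grid analysis, relative error bands). A seeded synthetic
    CGM generator makes the full pipeline testable without access-restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
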