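Package: sentinet
Title: Policy-Aware Spatio-Temporal Anomaly Surveillance for Regional Health Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating, modelling and monitoring region-level public
    health surveillance streams under time-varying policy interventions. The
    package provides a generative state-space simulator for coupled regional
    health summaries with injectable anomaly episodes, a hierarchical
    spatio-temporal transformer forecaster with graph-attention spatial
    aggregation and policy-aware gating, and a dynamic calibration layer that
    converts Gaussian forecast divergences into calibrated latent states,
    policy-conditioned forecast corrections and quantile-controlled alarm
    thresholds. Evaluation utilities cover ROC/F1/recall/MSE scoring, subgroup
    fairness bias gaps, and Gaussian residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
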