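Package: hcukf
Title: Online Hunt-Crossley Soft-Tissue Parameter Estimation with
    Adaptive Unscented Kalman Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint state-parameter estimation for the nonlinear
    Hunt-Crossley viscoelastic contact model from streaming
    force/displacement measurements, as produced by robotic palpation or
    indentation of soft tissue.  Implements the standard unscented Kalman
    filter and an adaptive strong-tracking variant that detects contact
    model error through the Mahalanobis distance of the innovation,
    estimates the innovation covariance with random (Dirichlet) weights
    over a sliding window, inflates the predicted state covariance by a
    trace-derived scaling factor, and redoes the measurement update.
    Includes a simulator for three canonical contact-model-error regimes
    (wrong initial parameters, simplified filter dynamics, transient
    prediction offset), Monte-Carlo drivers, force-reconstruction error
    metrics, delimited-text ingestion of user indentation records, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
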