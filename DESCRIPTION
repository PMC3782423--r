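Package: trajcomb
Title: Precision-Weighted Combination of Statistical and Dynamic
    Predictions in an Occluded-Trajectory Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an occluded-trajectory extrapolation task in which
    trajectory endpoints are drawn from a Gaussian distribution whose mean
    and variance jump independently every 20-40 trials, and implements the
    models an observer can bring to bear on it: a grid-based Bayesian ideal
    observer that tracks the non-stationary endpoint distribution (the
    "statistical" model), an ordinary-least-squares quadratic extrapolation
    of the current noisy trajectory (the "dynamic" model), and three
    combination rules (precision-weighted combination, fixed-ratio
    combination, and winner-take-all selection) fitted to responses by
    maximum likelihood and compared via log likelihood ratios and BIC.
    Also computes the trial-wise parametric regressors used in model-based
    neuroimaging of the task: log precisions, Gaussian Kullback-Leibler
    divergences, and response accuracy, with orthogonalization and
    BIDS-style events export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
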