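Package: coxstabsel
Title: Stability Selection for Cox Proportional-Hazards Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variable selection for right-censored survival data by stability
    selection with the lasso-penalized Cox partial likelihood as base learner.
    Implements an explicit construction of the regularization region: the
    null-model score statistic gives the smallest penalty yielding an empty
    model, a geometric grid spans the path, and the grid is truncated at the
    largest penalty at which the full-data lasso first reaches the
    average-selection budget implied by the expected-false-discovery bound.
    Subsampling the data and refitting the path yields per-variable selection
    probabilities; variables whose maximal probability over the truncated grid
    exceeds a threshold are selected. Includes survival-data simulators
    (autoregressive, latent-factor and shared-factor covariate designs with
    exponential hazards and calibrated uniform censoring), a replication
    harness with selection-accuracy metrics, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
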