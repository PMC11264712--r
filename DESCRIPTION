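Package: vbseq
Title: Value-Based Sequential Clinical Trial Design with Delayed Outcomes
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Design and monitoring of Bayesian value-based sequential
    clinical trials that compare two technologies on incremental net
    monetary benefit (INMB). Computes optimal stopping boundaries by
    backward induction for the conjugate-normal model with delayed
    (pipeline) observations, locates the prior-mean thresholds separating
    no-trial, one-stage and sequential designs, monitors accumulating
    trial data with sequential multiple imputation of missing costs and
    utilities, and evaluates operating characteristics by bootstrap
    resampling and Monte-Carlo simulation. Includes a calibrated
    synthetic patient-level data generator for a two-arm trial with an
    equivocal cost-effectiveness signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
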