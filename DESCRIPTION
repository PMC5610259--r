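Package: nsdmtest
Title: Robust M-Tests for Linear Models with Negatively Superadditive
    Dependent Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust M-estimation (least squares, least absolute deviation,
    Huber and user-supplied convex losses) and chi-square M-tests of linear
    hypotheses on regression coefficients when the errors form a negatively
    superadditive dependent (NSD) sequence.  Implements restricted and
    unrestricted M-fits via a null-space reparameterization, the M-criterion
    test statistic with consistent finite-difference estimation of the
    nuisance parameters, equal-tail chi-square calibration, local-alternative
    power via the noncentral chi-square distribution, a Gibbs-sampling NSD
    error generator, and a Monte Carlo harness for size and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
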