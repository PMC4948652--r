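Package: voitools
Title: Single-Step Estimation of the Expected Value of Partial Perfect
    Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Value-of-information analysis for cost-effectiveness models.
    Computes the expected value of perfect information (EVPI) and of partial
    perfect information (EVPPI) from probabilistic sensitivity analysis
    samples without nested Monte Carlo simulation, using mean plug-in for
    (multi)linear net-benefit functions, reparameterization, quantile-averaged
    Taylor-series approximation of conditional expectations, and restricted
    cubic spline regression on bin means.  Includes a nested Monte Carlo
    baseline with conditional inner sampling, deterministic quadrature
    oracles for validation, and a worked case study of fluid resuscitation
    for severe childhood malaria with a moment-matched reconstruction of the
    evidence-synthesis posterior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    tidyr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
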