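Package: phistar
Title: Integrated Information from the Mismatched-Decoding Perspective
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Practical measures of integrated information for multichannel
    time series. Implements the mismatched-decoding measure phi-star
    (the information lost when a system's parts are decoded as if they were
    independent), together with the comparison measures phi-I, phi-H
    (stochastic interaction), mutual information, and the original
    maximum-entropy phi for small discrete systems. Provides analytical
    Gaussian formulas based on covariance log-determinants, an exact
    enumeration engine for finite-state systems, a first-order
    autoregressive validation model with steady-state covariances via the
    discrete Lyapunov equation, set-partition enumeration with
    minimum-information-partition search, and covariance estimation from
    windowed multichannel recordings with bipolar re-referencing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
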