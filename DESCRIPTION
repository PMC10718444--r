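Package: tvbayesopt
Title: Time-Varying Bayesian Optimization for Closed-Loop Neurostimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-varying Bayesian optimization (TV-BayesOpt) for tracking a
    drifting optimal neurostimulation parameter, with a Gaussian-process
    surrogate built from composable spatial and temporal covariance functions
    (periodic, forgetting, forgetting-periodic) and a GP-LCB acquisition rule.
    Includes a coupled Kuramoto phase-oscillator model of a synchronous
    disease biomarker under phase-locked stimulation that serves as the
    closed-loop testbed, drift scenario generators, regret-based performance
    metrics, and sensitivity sweeps over the forgetting factor and the
    anticipated drift period.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
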