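Package: basketadd
Title: Adding New Baskets to Ongoing Basket Trials with EXNEX Borrowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for Bayesian basket trials with a
    binary endpoint in which new baskets are added part-way through the
    study. Implements posterior inference for the
    exchangeability-nonexchangeability (EXNEX) mixture model via a
    Metropolis-within-Gibbs sampler, four approaches for calibrating and
    analysing trials with added baskets (independent analysis, unplanned
    addition, and two planned-addition strategies), calibration of
    posterior-probability efficacy cut-offs under a global null scenario or
    robustly across several scenarios so that type I error is controlled on
    (weighted) average, and Monte Carlo simulators for fixed-scenario and
    random-scenario operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
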