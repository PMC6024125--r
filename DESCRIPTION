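Package: reintroIPM
Title: Integrated Population Models with Data-Derived Priors for
    Reintroduced Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint Bayesian inference for postrelease monitoring data from
    reintroduced populations: a Cormack-Jolly-Seber mark-resighting survival
    model and a Poisson log-link fecundity model with random effects are fitted
    simultaneously, optionally with informative priors derived from previous
    reintroductions.  Derived quantities include the finite rate of increase
    (lambda = s_a + s_j * f / 2), annual abundance (marked birds alive plus
    detection-corrected unmarked counts) and, under density-dependent
    fecundity, carrying capacity.  Includes a synthetic-data generator that
    runs the model forward, a sequential year-by-year precision analysis
    comparing informative and uninformative priors, and command-line entry
    points for simulation, fitting and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
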