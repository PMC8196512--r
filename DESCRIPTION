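Package: canopyk
Title: Estimating the Canopy Light Extinction Coefficient with Nonlinear Models
Version: 0.1.0
Authors@R:
    person("canopyk", "developers", email = "canopyk@example.org", role = c("aut", "cre"))
Description: Tools for estimating the light extinction coefficient k of the
    Beer-Lambert canopy light interception model fPARi = 1 - exp(-k * LAI)
    from observations of leaf area index and the fraction of intercepted
    photosynthetically active radiation. Implements and compares five
    estimation methods: least-squares, maximum likelihood under normal and
    beta likelihoods, a log-transformed through-origin linear model, and
    Bayesian estimation with a beta likelihood via random-walk Metropolis
    sampling. Includes a synthetic-data generator with the same hierarchical
    mean structure (per-genotype k, shared dispersion), observation-level
    mean-squared-error comparison reports, and command-line entry points for
    reproducible simulate/fit/compare runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
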