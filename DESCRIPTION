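Package: fdsynapse
Title: Information Processing in a Facilitation-Depression Synapse Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying information transmission at a depressing
    hippocampal basket-cell to pyramidal-cell GABAergic synapse. Implements a
    calcium-dependent facilitation-depression map driven by Poisson spike
    trains, closed-form stationary distributions for the presynaptic calcium
    concentration (gamma law) and for the stochastic fixed point of the
    normalized postsynaptic response (including a Gauss hypergeometric mean), a
    Katz-style stochastic quantal response model (binomial release with
    truncated-normal quantal amplitudes), and entropy / mutual-information
    estimators: histogram estimators with Freedman-Diaconis binning and
    k-nearest-neighbor (Kozachenko-Leonenko / KSG) estimators for
    higher-dimensional spike-history analyses. Includes experiment drivers that
    sweep stimulation frequency and compare a control parameter set with one
    describing muscarinic neuromodulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
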