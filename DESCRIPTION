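Package: rbnreservoir
Title: Random Boolean Network Reservoirs: Dynamics, Criticality, and Task Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis toolkit for reservoir computing with random
    Boolean networks (RBNs). Builds fixed in-degree reservoirs whose normal
    synaptic weights are parameterized by the coefficient of variation sigma*,
    maps sigma* to the excitatory-inhibitory balance b, characterizes
    free-running dynamics (BiEntropy of the binarized mean activity, attractor
    taxonomy, critical and re-entrant variance regions), generates white-noise
    memory and discrete Mackey-Glass prediction tasks, trains a sigmoid readout
    with full-batch ADAM, and orchestrates seeded parameter sweeps over
    (N, K, sigma*) with tidy tabular outputs and ggplot2 visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
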