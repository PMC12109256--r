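Package: connres
Title: Connectome-Based Echo State Networks for Chaotic Trajectory Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, weighted reservoirs from fruit-fly connectome
    export tables (neuron and synapse CSV/TSV following the FlyWire/CAVE
    schema), or from a statistically matched synthetic connectome generator,
    and evaluates them as leaky echo-state networks on forecasting of
    circularly-restricted three-body-problem trajectories. Implements the
    synapse quality filter and neurotransmitter sign assignment, two
    connected-subgraph selection criteria (most-connected and
    class-proportional), spectral-radius rescaling, randomized control and
    hybrid reservoir architectures, small-world topology metrics, ridge
    regression readout training, and a Monte Carlo comparison grid with
    Mann-Whitney and Bhattacharyya statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    deSolve,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
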