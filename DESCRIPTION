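Package: netcapacity
Title: Information Capacity and Rate of Noisy Linear Dynamical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much information a stable linear dynamical
    network can transmit per packet and per unit time when packets are
    delivered as impulses every T time units, the readout is corrupted by
    Gaussian noise, and activity left over from earlier packets acts as
    intersymbol interference. The capacity of a channel (A, B, C, T,
    sigma^2) is evaluated from its finite-horizon observability Gramian and
    a discrete-time infinite-horizon controllability Gramian through a
    log-determinant objective, maximised over trace-one positive
    semidefinite input covariances. Includes closed forms and bounds for
    scalar and normal networks, low- and high-noise asymptotics, chain and
    random non-normal network generators, non-normality and effective
    dimensionality diagnostics, and a connectome analysis pipeline with a
    synthetic fixture generator mirroring the C. elegans chemical-synapse
    data schema.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    deSolve,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
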