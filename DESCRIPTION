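Package: nmdagain
Title: Additive Gain from GluN2C/D-Like NMDA Conductances in a Model
    Auditory Midbrain Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Conductance-based simulation and analysis of how
    Mg2+-insensitive (GluN2C/D-like) NMDA receptor conductances shape
    rate and temporal coding in auditory midbrain neurons. Implements a
    Wang-Buzsaki-type fast-spiking neuron driven by periodic AMPA/NMDA
    synaptic input trains, rate and temporal modulation transfer
    functions, vector-strength and phase metrics for spike trains,
    double-exponential EPSC/EPSP waveform fitting and temporal-summation
    metrics, co-expression tabulation of per-cell RNAscope marker
    tables, and seeded synthetic-data generators for all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    signal,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
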