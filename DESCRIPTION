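Package: spikefidelity
Title: Distortion and Compensation Analysis for Spiking Network Models on
    Imperfect Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how network-level imperfections of analog
    and neuromorphic substrates distort the dynamics of spiking neural network
    models, and for compensating them. Provides a deterministic, seedable
    simulator for networks of adaptive exponential integrate-and-fire (AdEx)
    neurons with conductance-based synapses and Tsodyks-Markram short-term
    plasticity; builders for three benchmark cortical architectures (a layer
    2/3 attractor memory, a synfire chain with feed-forward inhibition, and a
    self-sustained asynchronous-irregular network on a torus); the three
    canonical distortion mechanisms (probabilistic synapse loss, clipped
    Gaussian synaptic weight noise, and uniform non-configurable delays);
    functionality criteria (attractor dwell times, pulse-packet state-space
    analysis and separatrix fits, firing-rate, irregularity, synchrony and
    spectrum statistics); and compensation strategies (weight rescaling,
    multi-source background, membrane-statistics matching, inhibition
    reshaping, mean-field gain-function time rescaling, and iterative
    per-neuron threshold calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
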