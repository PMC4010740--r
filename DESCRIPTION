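Package: dlgsim
Title: Dynamic Logic Gates in Neuronal Circuits with Elastic Response Latency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and closed-form analysis of feedforward neuronal
    circuits whose response latencies stretch with activity, so that their
    effective Boolean truth tables change over the course of repeated
    stimulation ("dynamic logic gates").  Provides an exact analytic engine
    based on delay-line arrangements, an event-driven spiking engine with
    temporal summation, refractoriness and inhibition windows, a
    conductance-based Hodgkin-Huxley population engine, builders for the
    canonical gate architectures (AND, OR, NOT, XOR, generalized AND,
    multi-mode), a truth-table classifier, and a rate-coded edge-detector
    application, together with YAML/JSON circuit serialization and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
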