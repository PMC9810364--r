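Package: phasecomm
Title: Dynamic Community Metrics for Phase-Based EEG Connectivity
Version: 0.1.0
Authors@R:
    person("Ivo", "Lanzetta", email = "ivo.lanzetta@example.org",
           role = c("aut", "cre"))
Description: Windowed weighted phase lag index (wPLI) connectivity from
    multichannel EEG, multilayer (temporal) modularity maximization with a
    Louvain-style optimizer, and the node/pair network dynamics metrics
    flexibility, allegiance and intermittence, together with bootstrap
    group comparisons, allegiance-thresholded intermittence difference
    curves, temporal coefficient-of-variation summaries, opinion-change
    questionnaire coding, and a synthetic-data generator with planted
    dynamic community structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
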