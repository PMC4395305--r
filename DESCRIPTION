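Package: braineff
Title: Brain Network Efficiency and Working-Memory Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking functional brain-network
    efficiency to working-memory performance across age groups. Generates
    block-modular BOLD-like time series, motion traces and 2-back session logs;
    preprocesses time series (band-pass filtering, nuisance regression, FD/DVARS
    motion scrubbing); builds density-matched binary functional networks from
    Pearson correlations (N = K^S matching, positive edges only); computes nodal
    and network local/global efficiency by breadth-first search; scores 2-back
    sessions with signal-detection d-prime and speed-accuracy RT controls; and
    fits bidirectional stepwise AIC linear models over main effects, pairwise
    interactions and quadratics, with deconstruction of the selected model into
    per-cohort prediction equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
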