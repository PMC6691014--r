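Package: flexembed
Title: Flexible Random-Walk Embedding of One Network into Another
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for embedding a large network A into a smaller network B
    with a stochastic assignment rule: unassigned source nodes are mapped to
    target locations in proportion to per-node attractiveness, and their
    neighbors follow attractiveness-weighted random walks on B with a
    per-step stopping probability q that tunes the locality of the coupling.
    Includes the exact stochastic simulator, mean-field moment equations for
    the assignment process, spectral machinery for the weighted walk
    (transition matrix, discounted propagator, stationary distribution),
    closed-form predictions for realized populations and the embedded
    weighted network, and ensemble tooling that compares simulation with
    theory. Useful as a null model of inter-layer coupling in multilayer
    networks, for example social networks embedded in geography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
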