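Package: dtfdecode
Title: Decoding Working-Memory Conditions from Directed Brain Connectivity
Version: 0.1.0
Authors@R: person("dtfdecode", "authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-trial effective connectivity from multichannel
    electrophysiology via multivariate autoregressive (MVAR) modelling and
    the directed transfer function (DTF), proportionally thresholded
    directed-graph metrics aggregated by brain region, Relief feature
    selection with linear support-vector decoding under repeated
    subsampling, permutation nulls, and binomial selection-frequency
    significance. Includes a synthetic multi-subject cohort generator with
    planted, band-specific directed couplings so the full pipeline is
    testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    rhdf5
Config/testthat/edition: 3
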