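Package: mbwiring
Title: Synapse-Level Wiring Analysis of the Mushroom-Body Alpha Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of dense, synapse-level
    connectomes of the Drosophila mushroom-body alpha lobe: ingestion and
    validation of synapse tables and SWC skeletons, aggregation into
    cell-type wiring tables, a Poisson null model of synapse counts with
    the minimum-expected-count chi-square convention, detection of spatial
    synaptic motifs (convergences, rosettes, KC<>KC>MBON triangles),
    dopamine volume-transmission coverage analysis, dendritic
    input-position profiles, and a seeded synthetic-connectome generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
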