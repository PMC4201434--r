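Package: pathsurf
Title: Environmental Outcome Surfaces of Duplicated Gene Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of a two-tier gene-regulatory cascade in
    which duplicated upstream and downstream gene copies, each with unimodal
    sensitivity to two environmental factors, jointly set the probability that
    a developmental or physiological outcome (e.g. germination) occurs.
    Computes outcome-probability surfaces over a two-factor environment grid
    for configurable pathway architectures (copy number, divergent
    environmental optima, pooled versus independent regulation), and analyses
    the surfaces: local-maximum detection, half-maximum breadth and precision
    metrics, total probability mass, and peak-to-optimum matching. Ships a
    registry of published figure-panel configurations, YAML/JSON run
    configuration, CSV/JSON output, optional heat-map rendering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
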