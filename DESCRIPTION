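Package: pinetviz
Title: Scriptable Protein-Protein Interaction Network Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Loads two-file protein-protein interaction datasets
    (interactions with aggregate and per-source evidence scores; protein
    features keyed by organism; optional expression values), filters them
    with cumulative-count prefilters, queries them with normal, explicit
    and recursive search modes, styles nodes and edges through an ordered
    rule engine (categorical palettes, quantitative color gradients,
    labels, sizes), lays networks out with a force-directed algorithm
    using one gravity well per organism or a deterministic circle layout,
    and exports SVG, PNG and CSV together with a replayable, shareable
    session state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    png,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
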