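Package: HiCNets
Title: Graph Representation, Force-Directed Layout and Organization
    Metrics for Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts normalized Hi-C whole-genome contact maps into
    undirected weighted graphs in which every genomic bin is a vertex and
    edges encode the linear chromosome backbone (weight 1/resolution) and
    the measured cis- and trans-chromosomal interaction frequencies.
    Provides two deterministic force-directed layout algorithms (stress
    majorization over weighted shortest-path target distances, and
    ForceAtlas2), chromosome-coloured SVG/PNG rendering with per-edge-type
    visibility, exporters to edge-list, adjacency-matrix, GraphML and GEXF
    formats for Cytoscape/Gephi, quantitative genome-organization metrics
    (cis/trans weight ratio, nearest-neighbour chromosome mixing,
    chromosome-territory separation), a synthetic contact-map simulator
    with power-law distance decay, territory structure, condensation and
    multiplicative noise, and a command-line interface covering the whole
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
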