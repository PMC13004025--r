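Package: topomotif
Title: Topology-Aware Census of Short Recycling Motifs in Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scans the cytoplasmic C-terminal regions of annotated membrane
    proteins for short linear recycling motifs (the bileucine LxxL core and
    related Retromer/Retriever/ESCPE-1/PDZ consensus motifs) using a compact
    pattern grammar with positional constraints. Provides readers for
    UniProt-style tabular topology annotations (TOPO_DOM/TRANSMEM), a
    topology engine that classifies C-termini and measures sequence distance
    to the nearest membrane segment, an end-to-end census pipeline with
    window, extracellular-exclusion and membrane-distance filters, formulas
    for quantifying receptor internalization, recycling and surface
    expression from fluorescence measurements, and a synthetic membrane
    proteome generator with planted motifs and exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
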