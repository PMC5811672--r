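Package: cellmapr
Title: Protein-Protein Interaction Networks Drawn Inside the Cell
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Headless visualization of protein-protein interaction (PPI)
    networks constrained by subcellular localization. Proteins are drawn as
    colored circles at seeded-random points inside named polygonal cell
    compartments (regions of interest on a cell image), with interaction
    edges and reliability labels overlaid. Ships a JSON protein-document
    database format, a GeoJSON-dialect cell-map format, deterministic
    hash-based compartment coloring, two viewer modes (all localizations
    versus primary localization), search and compartment filtering, SVG and
    PNG scene export, and a synthetic fixture generator so everything runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    withr,
    grDevices,
    graphics,
    stats,
    tools,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
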