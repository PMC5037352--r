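Package: difftree
Title: Differentiation Trees, Binary Lineage Codes, and CAST Alignment for
    Mosaic Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cell-lineage trees from mosaic embryos.
    Reads per-cell lineage tables, reorders rooted binary lineage trees into
    differentiation trees by relative daughter-cell volume, assigns binary
    lineage and differentiation codes, compares orderings with Hamming
    distances and isometric-graph coordinates, scores size-asymmetric
    divisions with a confidence-interval criterion, fits linear and power-law
    scaling of cell volume against lifetime and depth, encodes differentiation
    codes as depth-prefixed CAST tokens, and aligns CAST sequences between
    species with a Needleman-Wunsch style dynamic program. Includes a seeded
    branching-process simulator of mosaic embryogenesis for testing and null
    models, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
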