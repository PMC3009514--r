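Package: ribomotif
Title: Protein Interfaces with Ribosomal RNA Structural Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse how ribosomal proteins bind structural motifs
    of ribosomal RNA. Extracts protein-RNA contact surfaces from PDB/mmCIF
    structures with transparent distance rules, tabulates interface
    composition (atom types, phosphate-ribose-base partition, amino acid
    frequencies) with bootstrap standard errors, superposes tetraloop-anchored
    interfaces into a common frame by Horn's quaternion method and builds
    discretized polar interaction maps, and searches protein surfaces for the
    "tripod" binding-site motif: three convex amino-acid knobs at the vertices
    of a near-equilateral triangle cradling a single extruded nucleotide.
    Includes a ground-truthed synthetic-structure generator used throughout
    the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
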