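Package: molcolor
Title: Neighborhood-Specific Graph Coloring Identifiers for Metabolite Harmonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns every atom in a compound a symmetry-consistent identifier by
    a neighborhood-specific breadth-first graph coloring, derives ordered compound
    coloring identifiers from the atom identifiers, and uses them at tight and
    loose chemical specificity to harmonize compounds across metabolic databases,
    with EC-number validation of candidate correspondence pairs. Includes an MDL
    molfile V2000 reader/writer, a documented JSON graph dialect, reference-library
    aromatic substructure detection with Kekule normalization, geometric cis/trans
    perception for acyclic double bonds, an exact automorphism-orbit oracle, and
    deterministic generators for test molecules and paired toy databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
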