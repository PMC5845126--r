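Package: rxngrow
Title: Reaction-Rule-Based Fragment Growing for Structure-Based Lead Optimization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grows a query ligand inside a receptor pocket toward user-chosen
    interaction sites, where every growth step is a virtual application of a
    reaction rule extracted from atom-mapped chemistry, so that each proposed
    compound carries a concrete synthetic route.  Includes a molecular-graph
    core (SMILES/SDF/PDB readers, substructure matching, canonical keys),
    reaction-rule extraction from atom-mapped reactions, a building-block
    library, virtual synthesis, conformer generation and volume-overlap
    alignment, a deterministic pairwise interaction scorer with group
    efficiency, a beam-search growth engine with route export, and a
    self-contained synthetic fixture world (toy reaction set, block library,
    pseudo-receptor pocket with a planted optimum).
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
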