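Package: frasebot
Title: Fragment-Based Hit Finding with FRAgments in Structural Environments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mines protein-ligand complexes into a database of ligand fragments
    together with their protein residue environments (FRASEs), screens a target
    protein for matching residue-triplet environments encoded as many-hot bit
    strings, seeds database fragments into the target by three-point Calpha
    superposition, scores the nativeness of each seeded pose with a small neural
    network over 377-dimensional distance-weighted interaction fingerprints, and
    condenses surviving fragments into typed 3D pharmacophore queries for
    downstream library screening. Includes a synthetic-fixture generator so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
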