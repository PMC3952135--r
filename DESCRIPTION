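Package: incdock
Title: Incremental Flexible-Ligand Docking with Torsion-Tree Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Docking of large, flexible ligands (peptides, peptidomimetics and
    other compounds with more than six rotatable bonds) by incremental fragment
    extension. A ligand is decomposed into a torsion tree whose edges are
    rotatable bonds ranked by breadth-first traversal; an initial fragment
    spanning six rotatable bonds is docked with a genetic-algorithm sampler
    against a grid-based scoring field, and the fragment is repeatedly extended
    by a few bonds and re-docked -- freezing older torsions and re-exploring
    recent ones -- until the full ligand is placed. Supports positional
    restraints on a named ligand atom via a quadratic penalty added to the
    engine score during conformation selection, greedy RMSD clustering of the
    docked pool, and a six-pose report combining the lowest-scoring poses with
    cluster representatives. Includes synthetic chain-ligand and planted-minimum
    field generators so the whole pipeline is testable without external
    structures, and a command-line interface mirroring the library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
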