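Package: minspan
Title: Sparsest Null-Space Pathway Bases for Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes MinSpan pathways, the shortest set of linearly
    independent, thermodynamically feasible flux pathways spanning the
    null space of a metabolic network's stoichiometric matrix, by an
    iterative mixed-integer linear programming sweep solved with a
    built-in branch-and-bound over a bounded-variable simplex.  Includes
    the MaxSpan (densest) and RandSpan (randomly weighted) control bases,
    a brute-force sparsest-basis oracle for small networks, decomposition
    of sampled steady-state flux distributions into pathway weights,
    prediction of transcription-factor activity from significantly
    shifted pathways, and pathway-set statistics: co-occurrence
    correlation against interaction gold standards with ROC convex-hull
    AUC comparison, connection-specificity-index similarity across
    pathway definitions, and dual-perturbation gene-set algebra.  Models
    are read and written in SBML Level 3 (FBC) and a community JSON
    dialect.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
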