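Package: molautofix
Title: Molecule Auto-Correction with Chemical-Dictionary Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies and repairs defective molecular graphs. Molecules are
    featurized into hierarchical structural keys (atom, bond and circular
    environment keys) that are looked up in a frequency dictionary built from
    a reference library of drug-like molecules. Keys absent from the
    dictionary are "foreign"; a policy-guided tree search (breadth-first,
    greedy familiarity, UCT, A-star, regression-guided, or
    objective-preserving) applies prioritized single-edit graph perturbations
    until every key of the molecule is familiar, preferring output molecules
    structurally close to the input. Includes a lenient SMILES/SDF reader
    that accepts chemically invalid molecules, a seeded random "breaker" for
    benchmark input generation, and a scaled-down benchmark driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
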