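Package: rxnet
Title: Reaction-Rule Driven Exploration of Chemical Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Breadth-first generation of chemical structures by iterative
    application of reaction SMARTS rules. Implements constitutional isomer
    enumeration by canonical augmentation and by valence-conserving bond
    rearrangement, the analytic derivation of the minimal 19-rule bond
    rearrangement set, extraction of variable-diameter enzymatic reaction
    rules from atom-mapped reaction SMILES, stochastic inverse-QSAR search
    with tournament selection, and exact-mass peak annotation for metabolome
    completion. The graph engine (canonical labelling, subgraph matching and
    rule application) is implemented in C++; OpenBabel (via ChemmineR and
    ChemmineOB) is used for SMILES and InChI interconversion and MACCS
    fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
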