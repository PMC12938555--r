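Package: MorbiMap
Title: Ontology-Guided Multimorbidity Mapping from Literature-Derived
    Knowledge Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing shared and disease-specific
    multimorbidity architecture from heterogeneous biomedical knowledge
    graphs. Concept nodes associated with target diseases are ranked by
    HeteSim metapath relevance, normalized, and mapped to a harmonized
    13-category mechanistic ontology. Pairwise disease intersections are
    defined by a harmonic-mean threshold on normalized relevance scores and
    profiled by category counts, percentages, and Z-score enrichment against
    a global baseline. Category hierarchies are compared across diseases and
    intersections by rank correlation, assembled into an integrated priority
    landscape, and summarized by Borda rank aggregation with deterministic
    tie-breaking. A synthetic-data module generates semantic-network-style
    inputs with planted category structure and controllable cross-disease
    overlap so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
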