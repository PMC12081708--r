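Package: complexGO
Title: Gene-Ontology-Informed Multi-Objective Detection of Protein Complexes
    in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks with a decomposition-based multi-objective evolutionary algorithm
    (MOEA/D) whose objectives and mutation operator are driven by Gene
    Ontology semantics rather than topology alone. Provides a hybrid
    ancestor-DAG semantic similarity for GO terms with typed, weighted
    relations, best-match-average (BMA) functional similarity between
    proteins, two conflicting semantic objectives (intra-complex coherence
    and inter-complex separation), a functional-similarity-guided protein
    translocation mutation (FS-PTO), delta-thresholded complex-level
    evaluation against reference catalogs, degree-targeted noise perturbation
    of networks, and a planted-complex synthetic data generator for
    self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
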