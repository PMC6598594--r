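Package: phenoflow
Title: Boolean Network and Markov Chain Modeling of Cell Phenotype Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-tier framework for modeling phenotype decision making in cell
    populations, developed around epithelial-to-mesenchymal transition (EMT).
    Curated KEGG pathway maps (KGML) are converted into a signed Boolean
    network, a compact gene signature is extracted by a topological score
    combining out-degree and eccentricity ranks, single-state attractors are
    located under a constrained-asynchronous update scheme, and a discrete-time
    Markov chain over signature-defined phenotypes is derived from perturbation
    simulations. Population-level phenotype prevalences are then evolved under
    the chain and compared with expression data through fold changes, a
    concordance index, Bland-Altman limits of agreement and prevalence-weighted
    Jaccard-Needham distance trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
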