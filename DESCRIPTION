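Package: kinophore
Title: Structure-Based Pharmacophore Screening and Type-II Kinase
    Inhibitor Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for structure-based pharmacophore modelling and
    validation in kinase drug discovery. Perceives hydrogen-bond donor,
    acceptor and hydrophobic features in a protein binding site,
    enumerates and ranks candidate pharmacophore models, maps 3D ligands
    onto a model by tolerance-constrained correspondence search with
    rigid superposition, and validates models with Guener-Henry decoy-set
    statistics (yield, ratio, enrichment factor, goodness of fit) and
    ROC/AUC. Includes Lipinski Rule-of-5 profiling, geometric
    protein-ligand interaction detection (hydrogen bonds, pi-pi,
    pi-cation, pi-sigma, pi-alkyl, sulfur-X, van der Waals contacts), a
    back-to-front type-II kinase-inhibitor classifier, seeded synthetic
    generators for ligands, labelled screening libraries and
    planted-contact complexes, and an end-to-end screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
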