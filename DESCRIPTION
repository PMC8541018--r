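Package: netpharm
Title: Context-Specific Network Pharmacology for Multitarget Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline pipeline for context-specific network pharmacology of
    multitarget drugs: potency-based curation of drug-target affinity tables
    (Ki/EC50/IC50 below a physiological ceiling), three-way Venn intersection
    of drug targets with two disease-association gene lists, construction of a
    disease-restricted protein-protein interaction network from STRING-style
    scored edge lists with drug-anchored vertex-degree ranking and Markov
    clustering, and hypergeometric over-representation analysis of the common
    targets against GMT gene-set collections with Benjamini-Hochberg FDR.
    Includes seeded synthetic-data generators for every input format with
    machine-readable planted ground truth, and a consolidated pipeline report
    with provenance checksums.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
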