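Package: miRTarNet
Title: Integrative miRNA-Target Network Analysis for Drug-Resistance
    Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for identifying miRNA-target
    interactions behind acquired drug resistance from paired miRNA and
    mRNA expression studies. Implements three-group differential
    expression filtration (counts-per-million normalization, Welch t-test,
    one-way ANOVA, fold-change plus Benjamini-Hochberg filtering),
    cross-matching of in vitro and in vivo miRNA results, tissue-specific
    target prediction by inverse expression filtration against a
    target-prediction database, construction of integrated miRNA-gene
    interaction networks with top-decile hub detection and Cytoscape
    export, hypergeometric gene-set enrichment with activation z-scores,
    and xenograft tumor-response metrics (caliper volume, RECIST-style
    response calls, resistance index, Annexin V/PI quadrant
    classification). Ships a negative-binomial synthetic-data generator
    with planted miRNA-target repression so the full pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
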