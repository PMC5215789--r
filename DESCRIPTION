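Package: miRTriOmics
Title: Cancer-Related miRNA Ranking and Three-Factor Module Discovery
    from mRNA, Protein, and miRNA Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates matched mRNA, protein, and miRNA expression profiles
    to prioritise cancer-related miRNAs and to discover regulatory modules.
    miRNAs are ranked by an influence score that counts genes whose mRNA and
    protein expression both correlate strongly (top alpha percent of absolute
    rank correlations) with the miRNA. Three-factor modules of co-expressed
    mRNAs, proteins, and miRNAs are built by SAMBA-style biclustering of the
    differentially expressed mRNA matrix, permutation-test significance
    filtering, protein-protein-interaction expansion, and greedy inclusion of
    proteins and miRNAs under a linear-Gaussian Bayesian-network BIC score.
    Validation utilities cover catalogue ROC/AUC, expression-stratified
    survival comparison, pathway enrichment, and hypergeometric tests of
    direct, transcription-factor-mediated indirect, and co-regulatory
    miRNA-gene relationships. A synthetic-data generator with planted
    three-layer modules and serialised ground truth makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: GeneExpression, Network, NetworkInference, Survival, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
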