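Package: lncDA
Title: Predicting lncRNA-Disease Associations from Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers human disease associations for long noncoding RNAs
    (lncRNAs) from expression data alone, without training on known
    lncRNA-disease pairs. lncRNAs are partitioned by the tau tissue
    specificity index; tissue-specific lncRNAs are mapped to
    tissue-related disease classes (including multi-peak ties), while
    non-tissue-specific lncRNAs are scored against disease gene sets by
    hypergeometric enrichment of their Spearman co-expression
    neighbourhoods, with Bonferroni and Benjamini-Hochberg correction.
    Includes a rank-threshold leave-one-out ROC/AUC evaluation harness
    and a seeded block-structured synthetic data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, NetworkInference, GeneSetEnrichment, Software
RoxygenNote: 7.3.3
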