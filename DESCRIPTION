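Package: drugsig
Title: Derivation and Evaluation of Drug-Sensitivity Gene-Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives compact gene-expression signatures predictive of drug
    sensitivity (IC50) from cell-line panels. Implements a layered feature
    funnel - Pearson correlation screening, optional pathway and interaction-
    network filters, RReliefF ranking for continuous targets, Boruta
    shadow-feature confirmation with a random forest, and one-by-one backward
    elimination under a gradient-boosted-tree regressor tuned by repeated
    k-fold cross-validation - selecting the gene set that maximises the sum of
    two-fold and four-fold prediction accuracy on a held-out split. Includes
    blind-set evaluation metrics (fold accuracy, Pearson agreement, RMSE),
    z-score responder classification, tumor-type classification, hierarchical
    co-clustering, Wilcoxon differential expression, gene-list overlap and
    hypergeometric gene-set enrichment with Benjamini-Hochberg FDR control,
    plus a synthetic-data generator with planted causal genes for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
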