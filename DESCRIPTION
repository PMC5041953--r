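Package: lncfunsim
Title: Edge-Based Disease Semantic Similarity and lncRNA Functional
    Similarity from Disease Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes disease-disease semantic similarity on a rooted
    directed acyclic graph of disease terms (such as the MeSH Category C
    hierarchy) using an edge-based model that combines per-term
    information content with the most informative common ancestor and
    most informative leaf of each term pair.  Disease similarities are
    lifted to lncRNA-lncRNA functional similarity through a best-match
    group measure over each lncRNA's associated disease set.  A
    companion predictor (Gaussian interaction-profile kernels plus
    Laplacian-regularized least squares) and an evaluation harness
    (global leave-one-out and repeated k-fold cross-validation with
    ROC/AUC) let the similarity be exercised end-to-end on curated
    association tables or on synthetic data with planted modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
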