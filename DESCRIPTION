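Package: gwotalign
Title: Unsupervised Alignment of Similarity Structures with Gromov-Wasserstein Optimal Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares representational similarity structures (dissimilarity
    matrices over labeled items) with and without an assumed item
    correspondence. Provides an entropic Gromov-Wasserstein optimal transport
    solver with a log-domain Sinkhorn inner loop, a hyperparameter sweep over
    the entropy-regularization weight with random restarts, matching-rate
    evaluation of the optimal transportation plan against external labels,
    conventional representational similarity analysis (Spearman correlation of
    upper triangles), metric multidimensional scaling plus plan-weighted
    Procrustes rotation for aligned visualization, color-space baseline models
    (Euclidean RGB and CIEDE2000 on CIELAB), and synthetic generators of
    dissimilarity-structure pairs with known ground truth, including
    category-structured pairs that dissociate high inter-structure correlation
    from chance-level unsupervised matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    clue,
    farver,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
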