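Package: plastidrive
Title: Association Mapping of Plastid Inheritance Strength
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-wise correlation mapping of sequence divergence on aligned
    chloroplast genomes against plastid inheritance strength, with optional
    phylogenetic generalized least squares control; data-driven classification
    of inheritance strength from crossing data (partitioning-around-medoids
    silhouette selection followed by k-means); transmission-genetics and
    enzyme-assay statistics (percent-biparental progeny, Fisher's exact and
    Kruskal-Wallis tests, normalized carboxylase activity with paired t tests);
    and a repeated cross-validated LASSO model predicting inheritance strength
    from lipid levels. Includes seeded generators for synthetic plastome
    alignments, cross counts, and lipidome matrices with ground-truth
    manifests for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    cluster,
    glmnet,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
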