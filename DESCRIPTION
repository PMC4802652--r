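Package: pcahier
Title: Agglomerative Clustering of Single-Cell Profiles over Nested
    Principal-Component Subspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of nested cell-state hierarchies from
    single-cell expression matrices. Cells are first clustered by K-means in
    the subspace of the leading K-1 principal components; clusters are then
    merged agglomeratively using a multivariate-Gaussian likelihood evaluated
    at size-weighted pooled moments, with one trailing principal direction
    discarded after every merge so that each level of the hierarchy is tied
    to a reduced-dimensional representation of the data. Includes Adjusted
    Rand Index evaluation against reference labels, co-association consensus
    clustering across repeated stochastic runs, a generator of hierarchically
    structured synthetic expression data with known multi-level ground truth,
    readers and writers for delimited-text and Matrix Market expression
    matrices, Newick export of the merge tree, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
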