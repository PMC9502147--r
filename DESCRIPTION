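Package: schicminhash
Title: Single-Cell Hi-C Clustering with MinHash Approximate Nearest Neighbors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters populations of single-cell Hi-C contact matrices. Per-cell
    binned contact matrices are flattened into one very sparse cells-by-features
    matrix, an approximate Jaccard k-nearest-neighbor graph is built with MinHash
    locality-sensitive hashing and an inverse index (linear-time fit and query),
    the graph is embedded with PCA followed by UMAP under the Canberra metric,
    and cells are clustered with k-means, spectral, BIRCH or agglomerative
    clustering. Includes contact-decay profiles, cluster consensus matrices, a
    uniqueness-threshold detection-rate metric, a synthetic-population generator
    with known cluster structure, and readers/writers for scool containers and
    Matrix Market directories.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    rhdf5,
    stats,
    utils,
    uwot
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
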