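Package: sctad
Title: TAD-Like Domain Detection from Ultra-Sparse Single-Cell Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects TAD-like domain boundaries from ultra-sparse (single-cell)
    Hi-C contact matrices by consensus clustering over repeated non-negative
    matrix factorizations of overlapping sliding windows, with silhouette-based
    selection of the factorization rank. Includes a single-cell Hi-C simulator
    that samples contacts from 3D polymer coordinates, partition-similarity
    metrics (mutual information, adjusted mutual information, weighted
    similarity, variation of information, boundary-point distance),
    structure-quality indices (structure entropy, modularity), aggregate
    ChIP-seq peak enrichment at boundaries with permutation testing, and
    boundary-dynamics analyses across cell populations (variation classes,
    boundary popularity, cell-specific boundaries, unsupervised cell
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
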