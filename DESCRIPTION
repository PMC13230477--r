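Package: volcbir
Title: Volumetric Content-Based Image Retrieval with Late-Interaction
    Re-Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Content-based retrieval of volumetric (3D) medical images
    from per-slice embedding matrices: slice-level nearest-neighbour
    search (exact and a seeded HNSW graph index), hit-table aggregation of
    slice hits into volume rankings (Count-base, Max-Score, Sum-Sim),
    ColBERT-style late-interaction re-ranking (C-MIR) and reciprocal rank
    fusion, stage-stratified query/database cohort construction, and a
    seeded evaluation protocol (precision at k, average precision, paired
    Wilcoxon signed-rank comparisons).  Includes a synthetic
    embedding-cohort generator with planted organ/stage structure so the
    whole pipeline can be exercised end to end without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
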