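Package: gliaProfiler
Title: Morphometric and Transcriptomic Profiling of Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell morphometric profiling of microglia from binary
    masks (skeleton, convex-hull, fractal and lacunarity descriptors),
    statistical-learning analysis of the resulting feature tables (feature
    screening, PCA, elbow-selected k-means, nested cross-validated gradient
    boosted trees with gain importance), and companion transcriptomic tools
    (reads-per-million normalisation, moderated differential expression with
    fold-change/p/FDR filtering, directional gene-set overlap with Fisher's
    exact test and Baptista-Pike odds-ratio intervals, marker-panel purity,
    and delta-delta-Ct fold changes). Ships seeded synthetic generators for
    cell masks, feature tables, count matrices and direction-annotated gene
    sets so that every stage is testable without access to imaging or
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    withr,
    jsonlite,
    yaml,
    png,
    tiff,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
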