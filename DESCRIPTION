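Package: lfimc
Title: Incomplete Multiview Clustering via Late Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Late-fusion consensus clustering for multiview data with missing
    views. Each view (a symmetric kernel matrix over the same samples) is
    clustered independently on its visible instances with spectral-relaxed
    kernel k-means; the per-view partitions are encoded as zero-one indicator
    matrices and combined into a single clustering decision by alternating
    minimization of a masked k-means objective over the visible compressed
    representations. Includes the standard kernel-imputation baselines (zero,
    mean, k-nearest-neighbour and alignment-style filling followed by
    multiple-kernel k-means, plus a best-single-view oracle), a random
    view-missingness simulator, synthetic multiview kernel data generators,
    and clustering evaluation metrics (normalized mutual information and
    accuracy under optimal label matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
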