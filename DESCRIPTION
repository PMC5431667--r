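Package: longcnv
Title: Longitudinal Copy Number Variant Detection and Classification from
    SNP-Array logR Signals
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <maintainer@example.org>
Description: Detects copy number variants (CNVs) from SNP-array logR ratio
    signals sampled at three consecutive time points of the same subject,
    matches calls across time points, and classifies them as constant or
    de novo. Provides sample-level quality control (derivative log ratio
    spread, genomic-wave screening, PCA batch checks), circular-binary-style
    segmentation with a maximum pairwise segment p-value criterion and
    outlier removal, temporal trajectory classification with cumulative
    genome-coverage statistics, gene/QTL interval annotation with binomial
    and hypergeometric enrichment tests, qPCR relative-quantity validation,
    and a synthetic cohort generator emulating 50k-array logR matrices with
    planted CNVs for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
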