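Package: cyclegate
Title: Detecting and Removing Cell-Cycle-Composition Artifacts in Multi-Omics Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recognising and correcting artifacts that arise when
    cell populations with different cell-cycle phase compositions are compared.
    Implements replication-timing-aware correction of binned read depth and
    CNV segmentation, the two-population read-mixing algebra used to titrate
    the S-phase ratio in silico, cell-cycle phase assignment with
    correlation-based marker augmentation and precision/sensitivity/F1
    evaluation, phase-stratified differential expression with a two-part
    hurdle test, solo-WCGW methylation-delay summaries and Fisher-based DMR
    calling, and pseudo-mix open-chromatin set logic. A seeded synthetic-data
    generator reproduces the statistical structure these analyses assume so
    the whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    glmnet,
    withr,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
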