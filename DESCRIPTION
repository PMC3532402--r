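Package: tilemark
Title: Tiling-Array ChIP Analysis of Histone Lysine Methylation Marks
Version: 0.1.0
Authors@R: person("tilemark", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for ChIP-chip tiling-array data of histone
    modifications (H3K27me2/H3K27me3 and total H3): quantile normalization
    of probe-level PM-MM signals, IP/input log-ratio computation with
    optional adjustment for total H3, enriched-region detection with a
    two-state Gaussian hidden Markov model under gap/run/posterior rules,
    region-to-gene linkage with gene-type enrichment statistics (Fisher and
    chi-square tests, euchromatin/heterochromatin stratification,
    transposon-superfamily composition of long regions), fixed 15-bin
    metagene positional profiles, multi-mark K-means chromatin-state
    clustering, and Shannon-entropy tissue-specificity summaries.  A
    synthetic-data module generates probe layouts, planted enriched
    regions, gene annotations and expression matrices so the whole chain is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
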