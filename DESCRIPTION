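Package: msccdm
Title: Differential DNA Methylation from Methyl-Sensitive Cut Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for per-CpG methyl-sensitive restriction
    cut counts (digestion frequencies): library normalization, a
    CpG-island-calibrated unmethylated/methylated cutoff, pairwise Welch
    tests with mixed-directional false discovery rate (mdFDR) control,
    calling of tissue-specific differentially methylated sites (TS-DMS),
    lambda spike-in calibration of the empirical false discovery rate,
    genomic annotation relative to genes and CpG islands, odds-ratio and
    permutation-based fold-enrichment statistics, and correlation-distance
    epigenetic-signature clustering. Includes a negative-binomial
    synthetic-methylome generator with planted tissue-specific sites for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    ape,
    pheatmap,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
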