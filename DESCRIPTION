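Package: sporecheat
Title: Detection and Quantification of Fusion-Deficient Cheater Lineages in Filamentous Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for identifying and quantifying fusion-deficient
    "cheater" lineages arising during clonal propagation of Neurospora crassa.
    Provides a windowed structural-variant scan over clipped and discordantly
    flagged read alignments, a pairwise ancestor-versus-evolved variant filter
    for per-clone VCF call sets, an exact binomial test for parallel evolution
    of mutations within a gene class, conversion of duplexed qPCR Ct
    measurements into nuclear genotype frequencies, deconvolution of
    homokaryon and heterokaryon frequencies from selective plate counts,
    frequency-dependent competitive-fitness estimation, and synthetic-data
    generators that emulate each assay so the whole chain is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicAlignments,
    IRanges,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
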