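Package: peakperm
Title: Permutation Tests for Genomic Peak Co-Localization and IP-MS Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies enrichment or depletion of chromatin annotations at a
    fixed query peak set against a constrained random-placement null:
    length-matched shuffling of annotation peaks across the genome with
    blacklist/assembly-gap exclusion and optional tiling-probe density
    matching for ChIP-chip annotations, empirical p-values and log2
    observed/expected enrichment with Benjamini-Hochberg adjustment across
    annotations. Also provides pairwise peak co-localization summaries with a
    genome-binned Fisher exact test, a TMT IP-MS differential-enrichment
    stage (co-isolation filtering, total and median channel normalization,
    Student t-tests), and synthetic-data generators with known ground truth
    for all three stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
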