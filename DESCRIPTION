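Package: methagescan
Title: Sliding-Window Detection of Age-Associated DNA Methylation Change
    in Paired Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genomic regions whose DNA methylation changes
    consistently with age between paired samples from the same donors.
    Candidate 1000-bp windows over an array-style probe manifest are
    scored with Hodges-Lehmann pseudo-medians and a paired Wilcoxon
    signed-rank test, corrected by Benjamini-Hochberg, filtered on
    log2 ratio and an age-regression test, and merged into regions.
    Companion stages classify regions by CpG-island context and gene
    feature, test co-localization with chromatin tracks, profile
    single-molecule bisulfite read populations by age group, test
    disease-association enrichment of affected genes, and test global
    methylation trends. A fully seeded synthetic-data generator
    emulates a paired-donor cohort with planted age drift so every
    stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
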