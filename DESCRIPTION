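Package: popdiv
Title: SNP Sharing, Population Diversity, Archaic Admixture and
    Deletion Consensus from Multi-Sample VCFs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-level analyses of multi-sample variant call sets:
    per-sample genotype quality summaries (Het/Hom ratio, Ts/Tv ratio,
    CpG-context fraction, allele-frequency classification, novelty
    against known-variant catalogs), a pairwise SNP-sharing distance for
    intra-population diversity, unique-sharing matrices between
    populations with continental aggregation, a block-jackknifed
    ABBA/BABA D-statistic for archaic admixture restricted to bi-allelic
    transversions, consolidation of multi-caller structural-deletion
    calls with overlap-based novelty classification, and seeded
    Balding-Nichols simulators that generate every input format the
    analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
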