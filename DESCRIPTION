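Package: cclid
Title: Cancer Cell Line Identification from Small-Variant Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cancer cell lines (CCLs) from their small-variant
    fingerprints. Given a query variant profile (VCF) and one or more
    reference libraries of CCL profiles, cclid selects library-specific
    characteristic variants by an inclusion-weight threshold, scores every
    query/reference overlap with a binomial tail test, filters size-induced
    spurious matches with a beta-function statistic, and calls a reference
    profile identified when the confidence score, its rank, and the absolute
    overlap all pass their thresholds. The method is robust across DNA-seq,
    RNA-seq and panel-seq derived profiles. Includes a panel-sequencing
    simulator (BED interval restriction), a benchmarking harness
    (name-based gold standard, all-vs-all cross-validation, sensitivity /
    specificity / PPV / F1), a seeded synthetic multi-library profile
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
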