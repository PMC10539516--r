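Package: radsexmap
Title: Sex-Linkage Detection and Linkage-Map Utilities for RADseq Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify the sex-determination system (XY or ZW
    heterogamety) of a species from RADseq genotype data. Provides VCF-backed
    genotype matrices with marker and sample filtering, a Mendelian
    segregation-distortion filter for F1 mapping families tested against all
    seven bi-allelic segregation models, five genotype-frequency and
    presence/absence criteria for sex-linked markers with a label-permutation
    significance test, a codominant genotype-sex association scan with false
    discovery rate control, linkage-map cleanup, sex-averaged map merging and
    summary statistics, and a synthetic-data generator that emulates an F1
    mapping family with heterochiasmy and a sexed adult cohort carrying a
    sex-determining locus, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
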