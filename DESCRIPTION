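Package: serrata
Title: Germline and Somatic Exome Analysis for Familial Serrated Polyposis
Version: 0.1.0
Authors@R:
    person("serrata", "developers", email = "serrata@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of a familial gene-discovery
    workflow for serrated polyposis syndrome cohorts. Provides three-round
    germline variant prioritization with family co-segregation (rare-variant
    hard filters, cross-family exclusion, gene-set based function
    prioritization), Knudson two-hit integration of paired germline-somatic
    exomes (second-hit SNV/indel scan and exact-binomial allelic-imbalance
    loss-of-heterozygosity testing), and somatic mutational profiling
    (mutational burden with hypermutation classes, SBS96 and ID83 context
    classification, non-negative least-squares signature refitting against a
    catalog, and driver-gene reporting). Because cohort-scale human exomes
    cannot ship with a package, a first-class synthetic-cohort simulator with
    a known truth table exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
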