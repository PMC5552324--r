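Package: deepintron
Title: Deep-Intronic Variant Discovery in Hypertrophic Cardiomyopathy Gene Panels
Version: 0.1.0
Authors@R:
    person("Rui", "Valdez", email = "rvaldez@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for discovering and prioritizing deep-intronic
    candidate variants in whole-gene sequencing panels for hypertrophic
    cardiomyopathy (HCM). Implements k-of-n ensemble consensus over multiple
    variant callers with left-align/trim normalization and truth-set
    benchmarking (sensitivity and precision), multi-score threshold
    intersection of noncoding pathogenicity predictions (CADD, GWAVA,
    Genomiser, SPIDEX), splice-site distance and transcription-factor
    binding-site annotation, cohort allele-frequency enrichment against
    reference populations, compound-heterozygosity detection, and pedigree
    co-segregation summaries. Ships seeded synthetic-data generators for every
    input so the full pipeline is testable offline, plus a command-line
    interface with one subcommand per stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    rtracklayer
Config/testthat/edition: 3
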