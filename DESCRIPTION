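Package: sctcons
Title: Expression Consistency Analysis for Single-Cell Transcriptome Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions genes measured across multiple single-cell RNA-seq
    libraries (FPKM) into consistently expressed (detected in every library)
    and inconsistently expressed (detected in some but not all) groups,
    evaluates a housekeeping-gene reference panel, and profiles expression
    level and variability structure per group (coefficient-of-variation
    distributions, percentile-sampled log-expression profiles, group means
    and fold ratios, pairwise library correlations, multi-library set
    overlaps). Includes hypergeometric over-representation analysis of Gene
    Ontology terms (OBO 1.2 parsing, is_a DAG propagation, NCBI gene2go
    annotations) and of GMT pathway gene sets with coverage-percent
    filtering, plus a seeded synthetic-data generator emulating the
    three-stratum expression structure so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
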