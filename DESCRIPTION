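Package: mirflow
Title: Small RNA-Seq MicroRNA Quantification, Discovery and
    Pathway-Targeting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-group small RNA-seq
    studies of microRNA expression. Classifies collapsed reads through a
    quality-control cascade (length filter, exact genome matching, known
    miRNA panel, other non-coding RNA), normalizes counts to per-sample
    genome-matched totals (reads per million) and calls differential
    expression between two three-sample groups with Student's t-test and
    a fold-change gate. Discovers novel miRNA candidates from unannotated
    reads by locus grouping, precursor excision and a transparent
    Nussinov-style hairpin plausibility check; classifies candidate
    conservation by seed identity and overall mature-sequence identity;
    predicts targets by exact seed complementarity in 3'UTRs and scores
    pathway relatedness; clusters miRNA loci by genomic proximity; and
    cross-validates expression ratios against qPCR via the 2^-ddCt
    method. Ships a synthetic-data generator that emulates the study
    design end to end so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
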