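Package: hrescreen
Title: Differential ChIP-Seq Screening of Transcription-Factor Targets via
    Hypoxia Response Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a genome-wide screen for
    HIF-1alpha target genes from transcription-factor ChIP-Seq: read
    extension and coverage, Poisson local-lambda peak calling against an
    input control, exact-binomial differential enrichment between two
    exposure conditions, five-way genomic feature annotation with a
    TSS+/-2kb promoter window, hypoxia-response-element (HRE) motif
    screening of down-regulated promoter regions, hypergeometric pathway
    enrichment, and 2^-ddCt qPCR validation with ANOVA/LSD statistics.
    Ships a synthetic-data generator with planted ground truth so the whole
    screen is exercisable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
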