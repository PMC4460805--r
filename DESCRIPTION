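Package: lincte
Title: Transposable-Element Content in lincRNA Gene Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transposable-element-derived sequence (TES) in the
    promoters, exons and introns of long intergenic non-coding RNA (lincRNA)
    genes. Provides readers for RepeatMasker .out, BED12 and MAF files,
    strand-aware promoter/exon/intron partitioning with lincRNA selection
    filters, nucleotide-level TES coverage with two-sided Fisher exact tests
    on nucleotide contingency tables, classification of ancient versus
    lineage-specific TE insertions from cross-species pairwise alignments,
    Kimura 2-parameter evolutionary distances, expression summarisation
    (median log2 intensity, RPKM) with TES-content correlations, TATA-box
    positional scanning of core promoters, and a seeded synthetic-genome
    generator with planted truth so the whole pipeline is testable end to
    end without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
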