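Package: tsscompare
Title: Comparative Analysis of Transcription Start Sites Between Two Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing the primary transcriptomes of two related
    bacterial species from strand-specific 5'-end read-count tracks. Calls
    transcription start sites (TSSs) from replicated 5'-end tag counts with
    local-noise suppression and multiple-TSS filtering, assigns TSSs to
    downstream genes, finds orthologous gene pairs by reciprocal protein
    alignment, classifies each promoter region as conserved-with-TSS,
    conserved-without-TSS, orphan, or species-specific by reciprocal
    promoter-to-upstream alignment, compares 5' UTR lengths and sequences,
    profiles sequence conservation around translation starts, measures
    dinucleotide preference at the TSS, and discovers small-RNA homologs in
    synteny-bounded intervals with TSS-based expression support. Includes a
    synthetic genome-pair simulator with full planted truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
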