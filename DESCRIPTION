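Package: netprof
Title: Single-Nucleotide RNA Polymerase II Profiling from Nascent Transcription Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for nascent-transcription sequencing of the
    mNET-seq family, in which the 3' end of each nascent RNA fragment marks the
    last nucleotide incorporated by RNA polymerase II. The package filters
    aligned reads (multimappers, duplicates, improper pairs), extracts
    single-nucleotide-resolution polymerase positions from read or mate ends
    with strand flipping for paired-end chemistry, builds per-base strand-specific
    coverage tracks (bedGraph/bigWig), computes density-scaled metagene and
    anchored window profiles, quantifies transcriptional readthrough as the
    ratio of downstream to last-exon read density with Wilcoxon comparisons,
    and reproduces label-free IP-MS enrichment calls (peptide-count filtering,
    imputation, two-sided t-test volcano classification). A seed-deterministic
    synthetic-data generator emits annotation, aligned reads and LFQ tables
    with ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
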