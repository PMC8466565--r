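Package: organellotx
Title: Organelle Transcriptome Post-Transcriptional Processing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of post-transcriptional processing in plant organelle
    (chloroplast and mitochondrial) genomes from full-length transcript
    alignments and stranded site-level pileups. Classifies per-intron splice
    states of group II introns (cis and trans) on long-read and assembled
    transcripts, enumerates co-existing splicing intermediates, infers
    polycistronic transcription units and operons, identifies C-to-U RNA
    editing sites through a multi-evidence filter cascade with
    variant-allele-frequency (editing efficiency) estimation, characterises
    editing effects (codon changes, hydropathy shifts, -1 nucleotide
    preference, per-region efficiency), and detects splice-dependent editing
    near intron junctions. Includes a truth-known synthetic data generator so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
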