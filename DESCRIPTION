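Package: camptoseq
Title: Strand-Resolved Bisulfite RNA-Seq Analysis of Topoisomerase
    I-Perturbed Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the transcriptional response to camptothecin
    (CPT), a topoisomerase I poison, from strand-specific bisulfite RNA-seq
    and qPCR data. Implements strand-of-origin assignment of bisulfite-treated
    read pairs against C-to-T and G-to-A converted references, FPKM
    quantification with expression-class stratification, metagene sense-tag
    profiling over a scaled TSS-to-TES coordinate frame, a screen for genes
    accumulating 5'-truncated sense transcripts under CPT, DRIVE
    (DNA:RNA in vitro enrichment) percent-of-input quantification with
    RNase H1 background subtraction, and delta-delta-Ct relative
    quantification with exponential decay fitting of promoter antisense RNA
    turnover. A synthetic-data module generates toy genomes, annotations,
    bisulfite-converted paired reads with truth labels, and qPCR fixtures
    with known parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
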