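Package: pirnakit
Title: Ping-Pong, Target Prediction and Degradome Validation for piRNA Libraries
Version: 0.1.0
Authors@R:
    person("pirnakit", "developers", email = "pirnakit@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for PIWI-interacting RNA (piRNA) sequencing
    libraries: opposite-strand 5'-5' distance histograms and the ping-pong
    amplification z-score, per-5'-end median-length (3' trimming) comparison,
    nucleotide composition and genomic-origin assignment, collapsing of reads
    to 25-nt genome-derived piRNA representatives, ungapped antisense target
    scanning on transcripts with degradome-seq (PARE) cleavage validation,
    a negative-binomial stand-in differential-expression test with
    Benjamini-Hochberg correction, and the integration step that nominates
    piRNA-regulated genes. Includes a deterministic synthetic-data generator
    with a machine-readable ground-truth ledger so every stage is verifiable
    without access to real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
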