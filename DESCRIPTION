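Package: txpileup
Title: Nucleotide-Resolution Transcriptomic Pileup Tables from Genomic
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts genomically aligned RNA-seq reads (single- or
    paired-end, spliced) into transcript-space fragments with paired-end
    mate bridging, and summarizes them into per-nucleotide tables
    carrying coverage, read-start, read-end, base-call and deletion
    counts in both genomic and transcriptomic coordinates. Provides the
    derived metrics used in epitranscriptomic read-out analyses
    (start-to-coverage ratios for reverse-transcription stops,
    misincorporation rates for base-conversion chemistries), multi-sample
    table alignment, position-wise statistical tests, motif annotation,
    metagene and flank extraction, a coverage peak caller, a synthetic
    read-library simulator with injected modification effects, and a
    command-line pileup tool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
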