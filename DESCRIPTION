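Package: stopContext
Title: Stop Codon Usage and 3' Termination Context in Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify translation-termination codon usage (UAA, UAG,
    UGA) and the 3' downstream nucleotide context of stop codons in
    prokaryotic genomes, with emphasis on highly expressed genes (HEG) under
    translational selection. Provides strand-aware CDS and downstream-context
    extraction from FASTA + GFF3, stop-codon usage tables stratified by gene
    class and genome GC content, +4 nucleotide and downstream-codon profiling
    against the 1/64 chance expectation, tandem-stop detection, Pearson
    correlation of stop frequencies with GC, Student's t-test grouping of +4
    nucleotide frequencies, an optional codon adaptation index (CAI)
    classifier for HEG, and a seeded synthetic-genome generator with a
    machine-readable truth record for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
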