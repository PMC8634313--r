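Package: virtex
Title: Transposable Element Expression and Virus-Borne Insertions in
    Infected RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies transposable element (TE) family expression during
    infection by a large dsDNA virus from bulk RNA-seq, and detects host TE
    insertions expressed from viral genomes. Aggregates repeat-annotation
    fragments into TE copies with the classic >80 bp / >80% identity filter,
    computes TPM over genes and TE families jointly, calls differential
    expression with a negative-binomial Wald engine (or imported external
    results) under the adjusted p < 0.05 and |log2 fold change| >= 2 rule,
    classifies induced and repressed families against the 4/50 TPM cutoffs,
    detects TE-virus chimeric reads from split local alignments, and
    validates insertions by pairing 5' and 3' junctions into target-site
    duplication calls. A synthetic-data module generates viral genomes,
    planted insertions with TSDs, reads and count tables with known truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
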