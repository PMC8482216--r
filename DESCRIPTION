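Package: snoscout
Title: Discovery and Classification of Small Nucleolar RNAs from
    Size-Selected RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering unannotated small
    non-coding RNAs (50-200 nt) from size-selected ("medium") RNA-seq
    alignments. Reads are filtered against genomic feature annotation,
    clustered into candidate loci (>= 20 supporting reads), classified as
    C/D box snoRNA, H/ACA box snoRNA or scaRNA with a transparent
    rule-based motif and secondary-structure cascade, assigned to known
    sncRNA families with a k-mer-seeded local aligner, correlated with
    host-gene expression, and, for intergenic candidates, embedded in
    transcriptional units reconstructed from splice-junction evidence.
    A deterministic synthetic-data generator (toy genome, planted snoRNA
    loci of every class, simulated size-selected read pileups, correlated
    expression matrices) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
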