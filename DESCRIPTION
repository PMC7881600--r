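Package: kiresolve
Title: Resolving Complex CRISPR Knock-In Alleles from Long and Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the structure of complex CRISPR knock-in alleles at a
    targeted locus from long-read and short-read sequencing. Candidate long
    reads are recruited against a small bait set, fragmented into overlapping
    subreads and aligned to a composite reference to derive per-read block
    strings; block-string clusters are chained into allele structures (template
    copy number, plasmid backbone count, insertion length, cut-site indels).
    Junction sequences between allele blocks are discovered from short reads by
    edge k-mer baiting, abundance-based error trimming, greedy overlap assembly
    and alignment-based annotation (homology-arm boundaries, partial gRNA-site
    footprints, plasmid backbone fragments). Allele sequences are confirmed by
    center-star multiple alignment and majority-rule consensus. A seeded
    synthetic-data generator emulates a diploid locus carrying an NHEJ
    insertion allele and a multi-copy template/backbone concatemer allele plus
    a minor deletion derivative, with PacBio-like long reads and Illumina-like
    paired-end short reads, so the whole chain is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
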