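Package: snpshift
Title: Alignment-Free SNP Mapping from RNA-Seq by k-mer Count Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homozygous point mutations in RNA-seq data without read
    alignment. A database of k-mer variants is built from a reference
    transcriptome (each reference 22-mer accompanied by its three
    first-position substitution variants), exact closed-set k-mer counts are
    streamed from FASTQ reads per replicate, and candidate SNPs are called
    where counts shift from the reference k-mer to a variant k-mer in mutant
    replicates but not in wild type. Downstream utilities annotate coding
    effects (UTR/synonymous/missense/nonsense with HGVS-like shorthand),
    test gene-list overlap enrichment with an exact binomial tail, check
    segregation ratios by chi-square, and compute thiamin-vitamer fold
    changes, free fractions, Welch t-tests, and free-cofactor amplification
    under a bound-pool model. A seeded simulator generates EMS-mutagenized
    transcriptomes, error-bearing single-end reads, fold-change tables with
    planted overlaps, and replicate vitamer tables, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
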