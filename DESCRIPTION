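Package: sweepscan
Title: Selective Sweep Scans from Two-Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective sweeps between two population
    groups from a multi-sample VCF of biallelic SNPs.  Implements per-SNP
    fixation-index (Fst) computation from group allele frequencies,
    windowed mean Fst and nucleotide diversity (pi) in sliding windows,
    pi-ratio dual-threshold sweep calling with window merging and
    candidate-gene intersection, plus the supporting population-genetic
    statistics of a resequencing study: pairwise r2, LD-decay curves,
    PLINK-style LD pruning, p-distance and identity-score matrices, and
    neighbor-joining trees with bootstrap support.  A seeded
    Balding-Nichols two-population genotype simulator with known sweep
    intervals makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
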