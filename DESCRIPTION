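Package: gcescan
Title: Detection of Dual Genetic Code Expansion in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects natural genetic code expansion (pyrrolysine and
    selenocysteine) in bacterial genome assemblies and metagenome-assembled
    genomes. Provides readthrough-aware open reading frame calling under
    amber (UAG -> Pyl) and opal (UGA -> Sec) reassigned translation tables,
    rule-based cloverleaf folding to recognize the atypical Pyl and Sec
    tRNAs, detection of SECIS-like hairpins downstream of in-frame UGA
    codons, active-site verification of pyrrolysine proteins by global
    alignment against archaeal references, consensus and conserved-column
    utilities, inventories of the Sec and Pyl translation machinery from
    functional annotation tables with gene-neighborhood analysis, and
    fragment-based average nucleotide identity plus reciprocal-best-hit
    average amino acid identity between genomes. A seeded synthetic-genome
    generator plants recoded genes, atypical tRNAs, machinery cassettes and
    decoys with machine-readable truth tables so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
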