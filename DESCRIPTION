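Package: aviadapt
Title: Assembly Statistics, Decontamination, and Molecular Adaptation
    Analyses for Avian Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the computational stages of a de novo avian
    genome study as reusable, tested components: assembly summary
    statistics (Nx/Lx, GC content, per-base coverage, gene-element
    means), a multi-stage taxonomic contamination screen over BLAST
    tabular hits, pairwise codon-evolution statistics with
    Nei-Gojobori (1986) dN/dS, branch-site likelihood-ratio-test
    post-processing with Benjamini-Hochberg FDR, hypergeometric
    category enrichment with a permutation empirical p-value,
    ortholog family-size matrices with single-copy extraction and
    supermatrix concatenation, synteny block filtering with
    inversion classification, a consensus amino-acid substitution
    scanner, and seeded synthetic-data generators that plant known
    signals for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
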