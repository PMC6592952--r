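Package: cypome
Title: Fungal CYPome Discovery and RT-qPCR Relative Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining cytochrome P450 (CYP) complements from
    predicted fungal proteomes and for analysing RT-qPCR expression data of
    the discovered genes. Candidate CYPs are screened by global pairwise
    protein alignment against reference CYPs, validated by the three
    conserved P450 signature motifs (the haem-binding decapeptide
    FXXGXRXCXG, the PERF domain PXRX and the K-helix EXXR), filtered for
    partial gene models and classified into family/subfamily tiers by
    percent identity. The expression arm implements replicate concordance,
    standard-curve amplification efficiencies, geNorm reference-gene
    stability (M and pairwise variation V), efficiency-corrected
    multi-reference normalisation with delta-method error propagation,
    calibrated fold changes and Welch tests. Seeded generators produce
    synthetic proteomes with implanted signatures and synthetic
    quantification-cycle tables with known ground truth, so the whole
    pipeline is testable without external data. Ships a curated annotation
    table of the 32-member Cunninghamella elegans CYPome as a worked
    example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'seqio.R'
    'motif.R'
    'homology.R'
    'discovery.R'
    'qpcr.R'
    'simulate.R'
    'cypome-package.R'
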