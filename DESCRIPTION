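Package: seedcontrast
Title: Tissue-Contrast Multi-Omics Analysis of Embryo and Endosperm in
    Cereal Seeds
Version: 0.1.0
Authors@R:
    person("Seed", "Omics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for contrasting the two filial compartments of the
    cereal seed (embryo and endosperm) across proteome, transcriptome and
    metabolome layers. Implements label-free peptide-ion to protein
    quantification rollup, tissue partitioning into specific and common
    feature sets, median-threshold "favored" classification, z-score
    differential abundance on log2 ratios, presence-call consensus and
    equal-variance differential testing with Bonferroni control for
    microarray probe sets, dry-weight normalization and Student
    t-test/FDR contrasts for GC-MS metabolites, mRNA-protein log2-ratio
    concordance over unique probe-set/protein pairs, hypergeometric
    over-representation testing with Benjamini-Yekutieli control, and
    BLOSUM62 distance/neighbor-joining phylogeny for storage-protein
    families. Includes a synthetic-data generator that emulates the
    three-replicate two-tissue design so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
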