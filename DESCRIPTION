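Package: epishift
Title: Epiallele-Level DNA Methylation Heterogeneity and Entropy-Shift
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of read-level bisulfite sequencing methylation calls at
    loci of four adjacent CpGs (epialleles). Computes per-locus heterogeneity
    metrics (epipolymorphism, proportion of discordant reads, combinatorial
    entropy, mean methylation), calls entropy-shift loci (eloci) and the
    eloci-per-million (EPM) burden between paired disease states with a
    multi-control consensus rule, classifies epiallele pattern changes
    (disorder maintenance, selection, disorder, switch), annotates loci
    against promoters, CpG islands/shores/shelves and arbitrary region sets
    such as partially methylated domains, and relates promoter methylation
    heterogeneity to gene expression. Includes a synthetic cohort generator
    emitting epiread files, region sets, gene models and expression tables
    with known truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
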