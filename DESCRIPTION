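Package: alewifemix
Title: Microhaplotype Genotyping, Hybrid Classification, Kinship and
    Abundance Analysis for Secondary Contact Between Alewife Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse restoration-mediated secondary contact between
    anadromous and landlocked alewife (Alosa pseudoharengus) ecotypes with
    multiallelic microhaplotype markers. Provides a calibrated synthetic-data
    generator (Wright-Fisher drift between ecotypes, pedigree-structured
    crosses, amplicon read simulation, habitat-stratified seine surveys),
    phase-aware haplotype calling from SAM alignments with depth and
    depth-ratio filters and individual-level QC, population-genetic summaries
    (allelic richness, heterozygosity, Weir-Cockerham theta, PCA, best-SNP
    panel reduction), six-category hybrid classification with
    simulation-based power assessment, supervised two-population admixture
    estimation, close-kin log-likelihood-ratio power analysis with
    importance sampling, constrained likelihood parentage assignment with
    sibship summarisation, and habitat-stratified abundance estimation with
    bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
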