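Package: selpleio
Title: Polygenic Selection Scans and Antagonistic Pleiotropy at Disease Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for asking whether recent positive
    selection has acted on the loci underlying a complex disease, and whether
    the same alleles trade off against lifetime reproductive success
    (antagonistic pleiotropy). Implements extended haplotype homozygosity
    (EHH) and the integrated haplotype score (iHS) with empirical
    standardization in derived-allele-frequency bins and permutation p
    values; a per-gene mixed model regressing GWAS log odds on selection
    scores with the first linkage-disequilibrium (LD) eigenvector as a
    random effect; cis-eQTL regressions with expression-shuffling
    permutations and a Kolmogorov-Smirnov comparison of selected versus
    random SNPs; a kernel linear mixed model of adjusted lifetime
    reproductive success with a realized relationship matrix, MAF-binned
    permutation nulls, set- and gene-level (sum of chi-squares) enrichment
    tests; and an allele-harmonized antagonistic-pleiotropy classifier.
    A forward Wright-Fisher simulator with selective sweeps generates
    phased haplotype panels, GWAS summary statistics, expression and
    fitness phenotypes with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
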