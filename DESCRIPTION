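Package: sweepscan
Title: Selective Sweep Scans and Population Differentiation with a
    Built-In Wright-Fisher Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of selective sweeps and population differentiation
    from phased diploid genotypes. Implements an SFS-based composite
    likelihood ratio scan for selective sweeps with peak calling and gene
    assignment, cross-population extended haplotype homozygosity (XP-EHH)
    scanning with genome-wide normalization and quantile-based candidate
    selection, an accumulated squared allele-frequency-difference statistic
    with per-SNP relative contributions and empirical P-values, per-SNP
    Weir-Cockerham F_ST, and the f3 admixture statistic with weighted block
    jackknife standard errors.  A forward-time Wright-Fisher simulator with
    recombination, infinite-sites mutation, population splits, admixture
    events and additive selective sweeps provides multi-population phased
    data with full ground truth, so every scan can be validated against
    known simulation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
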