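Package: genecult
Title: Gene-Culture Coevolution Analysis of a Biallelic Variant in
    Native American Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-genetic inference chain behind a
    gene-culture coevolution study of the ABCA1 Arg230Cys (rs9282541)
    variant in the Americas: hierarchical analysis of molecular variance
    (F_CT, F_SC, F_ST) with permutation tests on single-SNP genotype
    counts, allele-age estimation by the Kimura-Ohta frequency method and
    by intra-allelic linkage-disequilibrium decay (moment and Bayesian
    MCMC estimators), structured-coalescent simulators for a hierarchical
    island model and a three-deme settlement demography, an FDIST-style
    F_ST-outlier test with kernel-density p-values, an ABC-style
    Euclidean-distance neutrality goodness-of-fit, and tie-corrected
    Spearman correlation of allele frequencies with archaeological maize
    (Zea) pollen dates.  Packaged fixtures carry the published genotype
    counts and pollen dates; forward and coalescent generators produce
    synthetic data with the same structure for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
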