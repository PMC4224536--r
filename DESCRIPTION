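Package: neratio
Title: Sex-Biased Effective Population Size Ratios from Nuclear and
    Mitochondrial Variation
Version: 1.0.0
Authors@R:
    person("Population Genetics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect sex differences in lifetime reproductive skew
    from neutral genetic variation. Estimates the population-scaled mutation
    parameter theta from diploid microsatellite genotypes (theta_n = 4 Ne mu_n)
    and from mitochondrial control-region sequence alignments
    (theta_m = 2 Nef mu_m) using moment estimators and a single-chain Bayesian
    coalescent MCMC (Kimura two-parameter pruning likelihood for sequences,
    Brownian-motion approximation to the stepwise mutation model for
    microsatellites), then propagates uniform priors on theta and on published
    marker mutation rates through the effective-size equations to a Monte-Carlo
    posterior of the ratio Ne:Nef and the percent reduction relative to the
    ideal random-mating expectation of 2. Includes a seeded single-population
    Kingman coalescent simulator for both marker types, the standard diversity
    indices (expected heterozygosity, haplotype diversity, nucleotide
    diversity, segregating-site summaries), and a reproducible end-to-end
    pipeline with FASTA/TSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
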