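Package: incursim
Title: Coalescent Simulation and Demographic Inference for Invasion
    Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the demographic history of recently
    introduced populations from reduced-representation SNP panels. Provides a
    structured-coalescent simulator with piecewise demography (bottlenecks,
    exponential growth, migration, population merges), a generator of
    study-like diploid genotype panels, the standard GBS variant and
    individual quality-control cascade with linkage-disequilibrium pruning,
    per-population heterozygosity and Weir-Cockerham F_ST statistics, folded
    site-frequency-spectrum construction with hypergeometric projection, and
    Monte-Carlo composite-likelihood fitting and ranking (delta likelihood,
    AIC) of competing incursion models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
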