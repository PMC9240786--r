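Package: gsintro
Title: Stochastic Simulation of Genomic Selection Breeding Programmes
    with Introgression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates multi-cycle cereal breeding programmes that combine
    genomic selection with a single introgression of external germplasm
    carrying major disease-resistance QTL. Provides a synthetic founder
    genotype generator with divergent allele-frequency profiles for an
    existing and an external population, a multi-trait multi-environment
    QTL architecture with correlated effects sampled via Cholesky
    factorisation, a meiosis engine (Poisson recombination, mutation,
    selfing, single seed descent), Bayesian ridge regression for marker
    effect estimation and GEBV prediction, selection indices with an
    optional major-allele-count term, and per-cycle evaluation of genetic
    gain, prediction accuracy, linkage drag and QTL allele-frequency
    trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
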