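Package: litterkin
Title: Microsatellite Parentage Analysis for Shark Litters
Version: 0.9.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic mating-system analysis of mother-litter
    microsatellite data in viviparous elasmobranchs. Implements
    diagnostic-locus species and F1-hybrid identification, per-locus
    population-genetic summaries with Monte-Carlo exact tests for
    Hardy-Weinberg equilibrium and linkage disequilibrium, minimum-sire
    reconstruction by exhaustive Mendelian search with likelihood-ranked
    father genotypes, Monte-Carlo power to detect multiple paternity
    (PrDM-style), Bayesian estimation of the population frequency of
    multiple mating, paternity-skew and fecundity statistics, and a
    synthetic-study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
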