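Package: crossim
Title: Simulation and Analysis of Meiotic Crossover Phenotypes in
    Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Johanne", "Halvorsen", email = "j.halvorsen@example.org",
           role = c("aut", "cre"))
Description: Tools for studying individual variation in meiotic
    recombination from SNP-array data in livestock-style pedigrees. The
    package simulates gametes under a stationary gamma-renewal crossover
    process with an interference-escape (Stahl) component, recovers
    crossover intervals from phased parental haplotypes and offspring
    genotypes, computes per-gamete crossover phenotypes (autosomal
    crossover count, intra-chromosomal allelic shuffling, distance from
    crossover to telomere), fits the Houseworth-Stahl interference
    likelihood by maximum likelihood, estimates heritabilities with a
    pedigree-based animal model by average-information REML, and runs
    mixed-linear-model association scans with a leave-one-chromosome-out
    genomic relationship matrix, genomic control, and Bonferroni
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
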