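Package: antcolonykin
Title: Colony Genetic Structure of Acacia-Ant Societies from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the genetic structure of social-insect colonies from
    biallelic SNP genotype matrices: filtering of individuals and loci,
    pairwise relatedness estimation (Lynch-Ritland and Queller-Goodnight
    moment estimators) with within- and between-colony aggregation,
    simulation-based estimator evaluation, maximum-likelihood sibship and
    parentage reconstruction for haplodiploid (and diplodiploid) broods
    under a two-class genotyping-error model, polygyny/polyandry/dominance
    indices, inferred-queen kinship classification, and the accompanying
    statistical comparisons. Includes a synthetic-colony generator with
    known pedigree ground truth so every stage can be validated against
    simulations, and a one-command pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
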