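Package: corekit
Title: Core Collection Construction and Evaluation for Germplasm SNP Panels
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@corekit.dev", role = c("aut", "cre"))
Description: Builds germplasm core collections from biallelic SNP genotype
    matrices under eight selection criteria (average/nearest-entry distances,
    expected heterozygosity, Shannon index, allelic coverage, CDmean,
    average genomic relatedness, D-optimality) and four stochastic optimizers
    (random descent, simulated annealing, hill climbing, genetic algorithm),
    singly or as weighted multi-objective combinations with optional
    forced-in accessions. Evaluates candidate cores against the whole
    collection with diversity and representativeness metrics (Shannon index,
    expected heterozygosity, mean Rogers distance, rare-allele retention,
    allelic coverage, Kullback-Leibler divergence of allele frequencies,
    eigenvalue-weighted principal-component correlation, phenotypic
    mean-difference ratio) and a composite z-score index. Scores cores on
    QTL-recovery power via seeded trait simulation and mixed-linear-model
    association scans with VanRaden kinship, discriminant-analysis structure
    covariates, genomic-control lambda and an effective-number-of-tests
    significance threshold. Includes population-structure tooling (PCA with
    Tracy-Widom axis selection, K-means/BIC clustering, DAPC memberships,
    Weir-Cockerham Fst) and a seeded Balding-Nichols panel generator so the
    full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
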