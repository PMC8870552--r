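Package: protwas
Title: Proteome Prediction Models and Proteome-Wide Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds aptamer-based protein abundance prediction models from
    cis genotype dosages using penalty-factor elastic net regression informed
    by Bayesian fine-mapping posterior inclusion probabilities, evaluates
    cross-population prediction transfer with Hudson F_ST, tests predicted
    proteins against GWAS summary statistics with the S-PrediXcan statistic,
    assesses colocalization of pQTL and GWAS signals with approximate Bayes
    factors, and triages associations through discovery, colocalization and
    replication criteria. Includes a multi-population synthetic-data
    generator (Balding-Nichols allele frequencies, Markov-chain linkage
    disequilibrium, sparse cis architecture, aptamer binding-affinity
    artifacts) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    knitr
Config/testthat/edition: 3
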