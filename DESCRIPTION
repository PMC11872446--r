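Package: pleiocoloc
Title: Cross-Phenotype Pleiotropy, Bayesian Colocalization, and Pseudobulk
    Differential Expression for GWAS-QTL Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates genome-wide association study (GWAS) and molecular
    quantitative trait locus (QTL) summary statistics to identify pleiotropic
    loci shared between two traits, test GWAS-QTL colocalization with
    per-variant approximate Bayes factors and posterior probabilities of the
    five standard hypotheses (PP0-PP4), nominate candidate causal genes via
    linkage-disequilibrium proxies, and quantify causal-gene expression
    changes in diseased tissue via donor-by-cell-type pseudobulk
    negative-binomial Wald tests.  A synthetic-data generator produces
    LD-structured genotype panels, summary statistics under shared or
    distinct causal-variant scenarios, and single-cell count matrices with
    planted fold changes, so that every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
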