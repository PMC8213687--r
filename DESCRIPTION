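Package: permdeg
Title: Exact Permutation Tests on Expression Quantiles for Differential
    Gene Expression in Airway Disease Sub-Phenotypes
Version: 0.1.0
Authors@R:
    person("Tom", "Mercer", email = "t.mercer@example.org",
           role = c("aut", "cre"))
Description: Differential gene expression for bulk RNA-seq count matrices
    using an exact (or seeded Monte-Carlo) permutation test on the absolute
    difference in the median, upper or lower quartile of TMM-normalized
    counts-per-million between two groups. Implements three-criterion DEG
    calling (FDR < 0.05, absolute quantile difference >= 10 cpm, fold change
    >= 1.5), sub-phenotype "unique DEG" set logic, confirmation-cohort
    direction concordance, a summed mitochondrial eight-gene expression
    signature with hierarchical clustering and surrogate-marker validation,
    qPCR delta-Ct copy-number arithmetic, and a negative-binomial synthetic
    cohort generator emulating a CT-phenotyped COPD case/control study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
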