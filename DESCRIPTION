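Package: drugpgs
Title: Polygenic Scores for Asthma Drug-Pathway Gene Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates weighted polygenic scores (PGS) for
    case-control studies of childhood asthma from a fixed panel of
    drug-pathway gene variants. Provides per-SNP log-additive logistic
    association, Hardy-Weinberg exact tests, LD-based pruning, weight
    derivation from in-sample effect estimates or from external GWAS
    summary statistics corrected by leave-one-cohort-out inversion of a
    fixed-effect inverse-variance meta-analysis (with LD-proxy
    substitution for untyped variants), weighted score computation,
    score-disease odds-ratio estimation, and ROC/AUC evaluation with
    DeLong or bootstrap confidence intervals. A genotype simulator with
    configurable allele frequencies, effect sizes, missingness and LD
    structure makes the whole pipeline testable without access to
    individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    metafor,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
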