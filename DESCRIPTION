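Package: prsphewas
Title: Polygenic Risk Score PheWAS and Two-Sample Mendelian Randomisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline from GWAS summary statistics and a genotyped
    cohort to phenome-wide association tables and causal-effect estimates.
    Covers fixed-effect meta-analysis with genomic control, genotype quality
    control (Hardy-Weinberg exact test, LD pruning, PCA covariates), polygenic
    risk scoring with plink score semantics, phecode/biomarker/reproductive
    factor PheWAS with statin adjustment, and two-sample Mendelian
    randomisation (IVW, MR-Egger, weighted median, MR-PRESSO, multivariable
    MR) with Steiger directionality filtering and group-wise FDR. A
    synthetic-data module generates biobank-like cohorts and paired GWAS
    summary statistics with known ground truth so every stage is testable
    without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
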