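---
title: "Methods: PRS-PheWAS and two-sample Mendelian randomisation on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS-PheWAS and two-sample Mendelian randomisation on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsphewas)
```

## What the package models

`prsphewas` implements the analysis chain that links a genetic liability to
a disease — here patterned on endometriosis — to the rest of the phenome
and to candidate causal mediators:

1. **Meta-analysis and weighting.** Cohort-level GWAS summary statistics
   are combined by fixed-effect inverse-variance meta-analysis, each cohort
   first deflated by genomic control. The resulting per-SNP effects serve
   as polygenic-score weights (in real use, externally derived posterior
   weights are consumed at this interface instead).
2. **Polygenic risk scoring.** Allele-aligned weighted dosage averages
   with plink `--score` semantics, z-scored within the analysis cohort.
3. **PheWAS.** The PRS z-score is tested against three trait sets in up to
   three cohorts (all females, males, and females without a disease
   diagnosis): logistic regression for phecode case/control status, linear
   regression for log-transformed blood/urine biomarkers after statin
   adjustment, and linear or proportional-odds models for female-specific
   reproductive factors. Each trait set carries its own Bonferroni
   threshold.
4. **Mendelian randomisation.** Harmonized exposure/outcome summary
   statistics pass instrument-strength (F > 10) and Steiger directionality
   filters before estimation by IVW, MR-Egger and the weighted median,
   with leave-one-out, MR-PRESSO and multivariable MR as sensitivity
   analyses, and Benjamini-Hochberg FDR applied within each direction and
   method.

Because the individual-level and restricted summary-level datasets such an
analysis normally consumes cannot be redistributed, the package carries a
first-class synthetic-data module whose outputs are written in the same
formats the readers consume, so every stage is testable with known ground
truth.

## The synthetic cohort

`gen_genotypes()` draws per-SNP allele frequencies uniformly from
`maf_range` and genotypes as Binomial(2, p) counts under Hardy-Weinberg
equilibrium, with independent missingness. Disease status follows the
standard liability-threshold model (`gen_disease()`): a standardized
genetic score over `n_causal` SNPs with normal effects contributes
`h2_liability` of the liability variance, normal noise the rest, and an
individual is a case when liability exceeds the standard-normal quantile at
1 − prevalence. The binary diagnosis scale of the emulated study is not
stated anywhere, so the liability threshold is a modelling choice — it is
the quantitative-genetics default and makes heritability and prevalence
independently configurable. The effect-size distribution of risk variants
is likewise unknown; it is standard normal by default and exposed through
the generator rather than fixed.

Comorbidities are generated as phecode flags translated into ICD10 codes
via the shipped synthetic phecode map (`gen_icd10_records()`). The map is a
deliberately small, synthetic stand-in for the PheWAS-catalog tables — a
real analysis should point `read_phecode_map()` at the full published
CSVs. Records for true disease cases draw only N80.1–N80.9 codes, and a
configurable fraction of unaffected individuals receives an N80.0-only
record, so the case-definition rule (N80.0 alone is adenomyosis, not a
case) is always exercised.

Biomarkers (`gen_biomarkers()`) are log-normal around a latent level, with
an optional log-scale shift per SD of genetic score. Statin users split
into the three strata the adjustment machinery needs — never users, users
from enrolment onward, and users at the first repeat visit only — and
on-treatment values are the latent value times `statin_effect` times
log-normal measurement noise. Reproductive factors
(`gen_female_factors()`) are drawn around population-typical centres
(menarche 13 ± 1.5 y, menopause 50 ± 4 y, cycle 28 ± 3 d, parity
Poisson(1.8), first birth 26 ± 4 y, birth weight 7.5 ± 1.2 lb) with
configurable score-linked shifts and a configurable fraction of
out-of-window values to exercise QC.

The two-sample generator (`gen_two_sample_sumstats()`) draws true
instrument effects with magnitudes in `gamma_range` (default 0.02–0.06)
and random signs, adds sampling noise at the large-sample standard error
`1/sqrt(2 p (1-p) n)`, and forms outcome effects as `true_b * gamma +
alpha + noise`. The pleiotropic term `alpha` is zero (`none`), zero-mean
(`balanced`), has a nonzero mean *relative to the exposure-increasing
allele* (`directional`), or correlates with instrument strength
(`inside_violating`). Tying the directional sign to `sign(gamma)` matters:
pleiotropy defined on an arbitrary allele orientation averages out after
MR-Egger's positive-exposure orientation and would leave the intercept
estimating zero. For the same reason gross outlier shifts
(`n_outliers` × `outlier_shift`, default 0.1 — more than 20 standard
errors at the default sample sizes) are aligned with the
exposure-increasing allele, so they bias the IVW slope coherently: the
regime outlier-removal methods are designed to repair. The incidental
pleiotropy scatter defaults to a quarter of the directional mean
(`pleiotropy_sd = 0.0025`), so the directional regime is
signal-dominated; with scatter comparable to the mean, no estimator could
attribute the intercept to direction rather than noise.

All generators route randomness through an explicit seed and restore the
caller's RNG state, so identically configured runs are byte-identical and
generation never perturbs user code.

**What the generator does not emulate:** linkage disequilibrium beyond
independent sites (the LD-pruning and clumping code is exercised with
constructed correlated columns instead), population stratification
confounding, sample overlap between exposure and outcome GWAS, and
ancestry structure. Passing tests therefore demonstrate correctness of the
estimators and plumbing under the stated models, not robustness to those
real-data complications.

## Analysis conventions and numerical choices

* **Genomic control.** `lambda = median(z^2) / qchisq(0.5, 1)`; standard
  errors are inflated by `sqrt(lambda)` only when `lambda > 1`
  (deflation is never applied), and p-values are recomputed from the
  corrected z.
* **Meta-analysis.** Per SNP, cohort alleles are harmonized to the first
  cohort carrying the SNP, resolving swaps by sign flip and strand flips
  by complement; irreconcilable records are dropped and reported. The
  combined sample size is the sum over contributing cohorts.
* **Phecode mapping.** An ICD10 code mapping to several phecodes keeps the
  numerically smallest phecode — a deterministic, auditable stand-in for
  an unstated upstream choice. Phecode controls are simply all
  individuals without the phecode; no exclusion-range logic is applied.
* **Hardy-Weinberg exact test.** Exact conditional test summing the
  probabilities of all heterozygote counts no more probable than the
  observed one; log-space normalization keeps totals in the hundreds of
  thousands stable.
* **LD pruning.** Greedy within sliding windows; of a correlated pair the
  lower-MAF member is removed, ties resolved toward the later position, so
  output is deterministic.
* **PCA.** Dosages mean-imputed, standardized by `sqrt(2p(1-p))`, exact
  SVD; component signs fixed by making the largest-magnitude loading
  positive.
* **PRS.** plink default semantics: counted-allele mismatch flips dosage
  to `2 − dosage`, missing dosage imputes at twice the effect-allele
  frequency, and the score averages over `2 × m` matched alleles
  (`average = FALSE` gives the plain sum).
* **z-scoring** uses the population (divide-by-n) standard deviation, so
  the transform is exactly idempotent.
* **Statin adjustment.** The correction factor is the within-sex mean of
  repeat/enrolment ratios among individuals starting statins between the
  two visits. Whether a biomarker responds to statins is decided from the
  same stratum by testing the covariate-adjusted mean log-ratio
  (the regression intercept after centring covariates) against zero at
  p < 0.05/n_traits. A regression of the log-ratio on the biomarker level
  would have no power against a multiplicative treatment effect, because
  the log-ratio is level-independent under that model; the adjusted-mean
  test targets exactly the quantity the correction divides out.
  Nonpositive biomarker values are rejected before the log transform
  rather than offset, which keeps failures visible.
* **Female-specific factors.** Plausibility windows: menarche 8–20 y,
  first live birth 14–43 y, menopause 40–63 y, cycle 22–36 d, first-child
  birth weight 3–12 lb; parity of 4+ collapses to one category; with
  repeated visits, parity takes the last record and every other factor
  the first. Linear factors are inverse-rank-normal transformed with Blom
  offsets `(rank − 3/8)/(n + 1/4)` (ties share average ranks); ordinal
  factors use a proportional-odds model (`MASS::polr`), and all p-values
  compare the t-value to a standard normal.
* **Instrument selection.** p < 5e-8 strictly, then greedy clumping in
  p-order: with LD information, a 10 Mb window at r² > 0.001; without it,
  a 1 Mb distance-only rule. These mirror the ecosystem defaults of the
  tooling this workflow is patterned on; the emulated study states only
  that independent genome-wide-significant SNPs were used.
* **Harmonization.** Outcome records align to the exposure effect allele
  (sign flips, strand complements); palindromic SNPs with exposure
  frequency in (0.42, 0.58) are dropped as strand-unresolvable.
* **IVW.** Fixed-effect weighted regression through the origin with
  weights `1/se_outcome²`; Cochran's Q on the ratio scale; when
  `Q/(k−1) > 1` the standard error inflates by `sqrt(Q/(k−1))`
  (multiplicative random effects). This matches the convention of
  reporting heterogeneity-robust significance while keeping the point
  estimate fixed-effect.
* **MR-Egger.** SNPs oriented to positive exposure betas, weighted
  regression with intercept; the model sigma is floored at 1 so reported
  uncertainty is never below the fixed-effect level; t-distribution
  p-values on k − 2 df.
* **Weighted median.** Inverse-variance ratio weights, linear
  interpolation of the cumulative weight function at 0.5, parametric
  bootstrap SE under an explicit seed.
* **MR-PRESSO.** The observed weighted residual sum of squares (each SNP
  against its leave-one-out IVW prediction) is compared to parametric
  simulations under the fitted model; the global p carries a +1
  pseudocount, while per-SNP outlier p-values use the plain empirical
  tail so that a gross outlier can clear the Bonferroni bar at moderate
  simulation counts. Outliers are only declared when the global test is
  significant; the distortion test compares the raw-vs-adjusted change
  against random same-size removals.
* **Multivariable MR.** Weighted least squares of outcome betas on the
  exposure-beta matrix without intercept; rank deficiency is an error
  naming the collinear exposures.
* **FDR.** Benjamini-Hochberg independently within each
  direction × method group.
* **Age covariate** is analysis year minus year of birth; the anchoring
  year is a configuration detail with no effect on within-cohort
  inference.

## Pipeline and problem sizes

`run_all()` executes the whole chain on synthetic data and writes TSV
tables plus a JSON manifest recording the seed, every threshold, and
retained/removed counts at each filter; reruns under the same
configuration are byte-identical. The shipped configuration uses a cohort
of 4,000 individuals × 300 SNPs and 30-instrument GWAS pairs of
200k/100k samples — sizes chosen so the full workflow and its
repeated-simulation checks (500-rep parameter recovery, 2,000-rep type-I
calibration, 200-rep outlier-robustness) complete in minutes on one CPU
while leaving Monte-Carlo error well inside the asserted tolerances.
Scaling the cohort up is a configuration change, not a code change.

## Known limitations

* The phecode map shipped under `inst/extdata/` is synthetic and tiny;
  real analyses must supply the published map.
* Ordinal model fits inherit `MASS::polr`'s initialisation and
  convergence behaviour; near-degenerate category distributions can fail
  to converge and surface as errors rather than silent drops.
* The Steiger filter uses the z²/(z² + n − 2) variance approximation,
  which ignores allele frequencies; with very unequal trait scales it is
  conservative rather than exact.
* No LD-aware clumping from a reference panel: supplied pairwise LD or
  the distance-only rule are the only options, and GSMR-style analyses
  that need an individual-level LD reference are out of scope.
* The biomarker PheWAS rejects nonpositive values; assays with values
  below a detection limit need upstream handling before entering the
  model.
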