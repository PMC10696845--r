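# Shared fixture builders: everything is generated in code, no stored data.

# Minimal sumstats table with sensible defaults, overridable per column.
make_sumstats <- function(k = 3, snp_id = sprintf("rs%03d", seq_len(k)),
                          chrom = rep("1", k),
                          pos = seq_len(k) * 100000,
                          effect_allele = rep("A", k),
                          other_allele = rep("G", k),
                          eaf = rep(0.3, k),
                          beta = rep(0.1, k), se = rep(0.02, k),
                          p = NULL, n = rep(10000, k),
                          trait = "trait", cohort = "cohort") {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      effect_allele = effect_allele,
                      other_allele = other_allele, eaf = eaf,
                      beta = beta, se = se, p = p, n = n,
                      stringsAsFactors = FALSE),
           trait = trait, cohort = cohort)
}

# Minimal harmonized MR input.
make_mr_input <- function(beta_exposure, beta_outcome,
                          se_exposure = rep(0.01, length(beta_exposure)),
                          se_outcome = rep(0.01, length(beta_exposure)),
                          n_exposure = rep(1e5, length(beta_exposure)),
                          n_outcome = rep(1e5, length(beta_exposure)),
                          eaf = rep(0.3, length(beta_exposure))) {
  k <- length(beta_exposure)
  mr_input(data.frame(
    snp_id = sprintf("rs%03d", seq_len(k)),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    p_exposure = 2 * stats::pnorm(-abs(beta_exposure / se_exposure)),
    n_exposure = n_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    p_outcome = 2 * stats::pnorm(-abs(beta_outcome / se_outcome)),
    n_outcome = n_outcome, eaf = eaf, stringsAsFactors = FALSE))
}

# Harmonized MR input straight from the two-sample generator.
simulate_mr_input <- function(seed, ...) {
  sim <- gen_two_sample_sumstats(synth_mr_config(seed = seed, ...))
  harmonize(sim$exposure, sim$outcome)
}

# Naive O(n^2) Benjamini-Hochberg: adjusted p_i is the minimum over all
# j with p_j >= p_i of n * p_j / rank(p_j), capped at 1.
bh_naive <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    min(1, min(vapply(seq_len(n), function(j) {
      if (p[j] >= p[i]) n * p[j] / r[j] else Inf
    }, numeric(1))))
  }, numeric(1))
}

# The synthetic phecode map shipped with the package.
load_phecode_map <- function() {
  read_phecode_map(
    system.file("extdata", "synthetic_icd10_phecode_map.csv",
                package = "prsphewas"),
    system.file("extdata", "synthetic_phecode_definitions.csv",
                package = "prsphewas"))
}
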