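#' Configuration for a synthetic biobank-like cohort
#'
#' Bundles the parameters of the cohort generator: genotypes under
#' Hardy-Weinberg equilibrium, a liability-threshold disease, phecode-coded
#' comorbidities, biomarkers perturbed multiplicatively by statin use, and
#' female-specific reproductive factors. All downstream generators consume
#' this object so a whole cohort is reproducible from one seed.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of variants.
#' @param maf_range Length-2 numeric, minor-allele-frequency range in
#'   (0, 0.5]; per-SNP frequencies are drawn uniformly from it.
#' @param missing_rate Fraction of dosages set missing, in [0, 1).
#' @param prevalence Disease prevalence on the liability scale, in (0, 1).
#' @param h2_liability Heritability of liability, in [0, 1].
#' @param n_causal Number of causal SNPs (<= n_snps).
#' @param statin_usage_rate Fraction of individuals ever on statins.
#' @param statin_effect Multiplicative effect of statin use on affected
#'   biomarkers (> 0); 0.75 means a 25% reduction on treatment.
#' @param seed Integer seed; every generator derives its stream from it.
#' @return An object of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_individuals = 10000L,
                                n_snps = 1000L,
                                maf_range = c(0.05, 0.5),
                                missing_rate = 0.01,
                                prevalence = 0.05,
                                h2_liability = 0.3,
                                n_causal = min(100L, n_snps),
                                statin_usage_rate = 0.15,
                                statin_effect = 0.75,
                                seed = 1L) {
  if (!is_count(n_individuals) || !is_count(n_snps)) {
    stop_param("n_individuals and n_snps must be positive integers")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_param("maf_range must lie within (0, 0.5] and be ordered")
  }
  if (!is_fraction(missing_rate) || missing_rate >= 1) {
    stop_param("missing_rate must be in [0, 1)")
  }
  if (!is_fraction(prevalence, open_lower = TRUE, open_upper = TRUE)) {
    stop_param("prevalence must be in (0, 1)")
  }
  if (!is_fraction(h2_liability)) {
    stop_param("h2_liability must be in [0, 1]")
  }
  if (!is_count(n_causal) || n_causal > n_snps) {
    stop_param("n_causal must be a positive integer <= n_snps")
  }
  if (!is_fraction(statin_usage_rate)) {
    stop_param("statin_usage_rate must be in [0, 1]")
  }
  if (!is.numeric(statin_effect) || statin_effect <= 0) {
    stop_param("statin_effect must be strictly positive")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_snps = as.integer(n_snps),
         maf_range = as.numeric(maf_range),
         missing_rate = missing_rate,
         prevalence = prevalence,
         h2_liability = h2_liability,
         n_causal = as.integer(n_causal),
         statin_usage_rate = statin_usage_rate,
         statin_effect = statin_effect,
         seed = as.integer(seed)),
    class = "synth_cohort_config"
  )
}

#' Configuration for paired two-sample GWAS summary statistics
#'
#' Parameters of the exposure/outcome summary-statistic generator used to
#' exercise the Mendelian-randomisation estimators with known ground truth.
#'
#' @param k_instruments Number of independent instruments (>= 2).
#' @param true_b True causal effect of the exposure on the outcome.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`. Controls the per-SNP direct (pleiotropic) effects
#'   on the outcome: absent, zero-mean, non-zero mean, or correlated with the
#'   instrument strength (violating the InSIDE assumption).
#' @param pleiotropy_sd Standard deviation of the pleiotropic effects.
#' @param pleiotropy_mean Mean pleiotropic effect under `"directional"`.
#' @param n_exposure,n_outcome GWAS sample sizes (>= 100).
#' @param n_outliers Number of SNPs given gross pleiotropic shifts on top of
#'   the mode, to exercise outlier detection.
#' @param outlier_shift Magnitude of the gross shifts (outcome effect scale).
#' @param gamma_range Range of true instrument effect magnitudes on the
#'   exposure; signs are random.
#' @param seed Integer seed.
#' @return An object of class `synth_mr_config`.
#' @export
synth_mr_config <- function(k_instruments = 30L,
                            true_b = -0.2,
                            pleiotropy_mode = c("none", "balanced",
                                                "directional",
                                                "inside_violating"),
                            pleiotropy_sd = 0.0025,
                            pleiotropy_mean = 0.01,
                            n_exposure = 200000L,
                            n_outcome = 100000L,
                            n_outliers = 0L,
                            outlier_shift = 0.1,
                            gamma_range = c(0.02, 0.06),
                            seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is_count(k_instruments) || k_instruments < 2) {
    stop_param("k_instruments must be an integer >= 2")
  }
  if (!is_count(n_exposure) || n_exposure < 100 ||
      !is_count(n_outcome) || n_outcome < 100) {
    stop_param("GWAS sample sizes must be integers >= 100")
  }
  if (n_outliers < 0 || n_outliers > k_instruments) {
    stop_param("n_outliers must be in [0, k_instruments]")
  }
  if (length(gamma_range) != 2L || any(gamma_range <= 0) ||
      gamma_range[1] > gamma_range[2]) {
    stop_param("gamma_range must be positive and ordered")
  }
  structure(
    list(k_instruments = as.integer(k_instruments),
         true_b = true_b,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_sd = pleiotropy_sd,
         pleiotropy_mean = pleiotropy_mean,
         n_exposure = as.integer(n_exposure),
         n_outcome = as.integer(n_outcome),
         n_outliers = as.integer(n_outliers),
         outlier_shift = outlier_shift,
         gamma_range = as.numeric(gamma_range),
         seed = as.integer(seed)),
    class = "synth_mr_config"
  )
}

#' Generate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Per-SNP allele frequencies are drawn uniformly from `cfg$maf_range`,
#' genotypes are sampled as Binomial(2, p) counts of the counted allele, and
#' entries are set missing independently at `cfg$missing_rate`.
#'
#' @param cfg A [synth_cohort_config()].
#' @return A `genotype_matrix`: list with `dosages` (individuals x SNPs,
#'   values 0/1/2/NA), `variants` (snp_id, chrom, pos, counted_allele,
#'   other_allele, freq) and `ids`.
#' @export
gen_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  with_seed(child_seed(cfg$seed, 1L), {
    n <- cfg$n_individuals
    m <- cfg$n_snps
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    dos <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
    if (cfg$missing_rate > 0) {
      dos[stats::runif(n * m) < cfg$missing_rate] <- NA_integer_
    }
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
    variants <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(m)),
      chrom = as.character(1L + (seq_len(m) - 1L) %% 22L),
      pos = 1000L + 5000L * (seq_len(m) - 1L) %/% 22L,
      counted_allele = a1,
      other_allele = unname(a2),
      freq = maf,
      stringsAsFactors = FALSE
    )
    genotype_matrix(dos, variants, sprintf("id%06d", seq_len(n)))
  })
}

#' Simulate a liability-threshold disease on a genotype matrix
#'
#' A subset of `cfg$n_causal` SNPs receives normal effect sizes; the genetic
#' score over standardized dosages is scaled to explain `cfg$h2_liability` of
#' the liability variance, normal noise supplies the rest, and individuals
#' whose standardized liability exceeds the (1 - prevalence) normal quantile
#' are cases.
#'
#' @param G A `genotype_matrix`.
#' @param cfg A [synth_cohort_config()].
#' @return List with `status` (0/1 per individual), `liability`,
#'   `genetic_value` (the true standardized genetic score) and `effects`
#'   (data frame of causal snp_id, effect allele, beta).
#' @export
gen_disease <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"),
            inherits(cfg, "synth_cohort_config"))
  if (cfg$n_causal > ncol(G$dosages)) {
    stop_param("n_causal exceeds the number of SNPs in G")
  }
  if (cfg$h2_liability > 1) stop_param("h2_liability must be <= 1")
  with_seed(child_seed(cfg$seed, 2L), {
    m <- ncol(G$dosages)
    causal <- sort(sample.int(m, cfg$n_causal))
    beta <- stats::rnorm(cfg$n_causal)
    X <- G$dosages[, causal, drop = FALSE]
    p <- G$variants$freq[causal]
    # mean-impute missing dosages, standardize by sqrt(2p(1-p))
    X <- sweep(X, 2L, 2 * p)
    X[is.na(X)] <- 0
    X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
    g <- drop(X %*% beta)
    g_std <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g
    h2 <- cfg$h2_liability
    liab <- sqrt(h2) * g_std +
      sqrt(1 - h2) * stats::rnorm(nrow(X))
    liab <- (liab - mean(liab)) / stats::sd(liab)
    thr <- stats::qnorm(1 - cfg$prevalence)
    list(status = as.integer(liab > thr),
         liability = liab,
         genetic_value = g_std,
         effects = data.frame(snp_id = G$variants$snp_id[causal],
                              effect_allele = G$variants$counted_allele[causal],
                              beta = beta,
                              stringsAsFactors = FALSE),
         threshold = thr)
  })
}

#' Generate per-individual ICD10 records from phecode status flags
#'
#' Individuals flagged for a phecode receive one of the ICD10 codes mapping
#' to it; random noise codes are added at `misdiagnosis_rate`. Pass flags for
#' the endometriosis phecode plus an `adenomyosis_only` column to emit N80.0
#' without other N80.x codes, exercising the case-definition logic.
#'
#' @param status A data frame with column `id` plus one logical/0-1 column
#'   per phecode (column name = phecode as character). An optional
#'   `adenomyosis_only` column forces an N80.0-only record.
#' @param map A `phecode_map` from [read_phecode_map()].
#' @param misdiagnosis_rate Expected number of random extra codes per
#'   individual.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `icd10`.
#' @export
gen_icd10_records <- function(status, map, misdiagnosis_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(status), "id" %in% names(status),
            inherits(map, "phecode_map"))
  phe_cols <- setdiff(names(status), c("id", "adenomyosis_only"))
  missing_codes <- setdiff(phe_cols, map$icd10$phecode)
  if (length(missing_codes) > 0) {
    stop(sprintf("phecode(s) absent from map: %s",
                 paste(missing_codes, collapse = ", ")), call. = FALSE)
  }
  with_seed(seed, {
    codes_for <- function(phe) map$icd10$icd10[map$icd10$phecode == phe]
    out <- vector("list", length(phe_cols) + 2L)
    for (i in seq_along(phe_cols)) {
      phe <- phe_cols[i]
      flagged <- status$id[as.logical(status[[phe]])]
      if (length(flagged) == 0) next
      pool <- codes_for(phe)
      # the endometriosis phecode must never be represented by N80.0 alone:
      # flagged true cases draw from the N80.1-N80.9 codes
      if (any(grepl("^N80", pool))) pool <- setdiff(pool, "N80.0")
      out[[i]] <- data.frame(id = flagged,
                             icd10 = sample(pool, length(flagged),
                                            replace = TRUE),
                             stringsAsFactors = FALSE)
    }
    if ("adenomyosis_only" %in% names(status)) {
      adn <- status$id[as.logical(status$adenomyosis_only)]
      if (length(adn) > 0) {
        out[[length(phe_cols) + 1L]] <-
          data.frame(id = adn, icd10 = "N80.0", stringsAsFactors = FALSE)
      }
    }
    if (misdiagnosis_rate > 0) {
      n_noise <- stats::rpois(1L, misdiagnosis_rate * nrow(status))
      if (n_noise > 0) {
        pool <- setdiff(map$icd10$icd10, c("N80.0"))
        out[[length(phe_cols) + 2L]] <-
          data.frame(id = sample(status$id, n_noise, replace = TRUE),
                     icd10 = sample(pool, n_noise, replace = TRUE),
                     stringsAsFactors = FALSE)
      }
    }
    rec <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(rec)) {
      rec <- data.frame(id = character(), icd10 = character(),
                        stringsAsFactors = FALSE)
    }
    rec <- unique(rec)
    rec[order(rec$id, rec$icd10), , drop = FALSE]
  })
}

#' Generate a paired-visit biomarker table with statin strata
#'
#' Each individual gets a latent log-normal biomarker level, optionally
#' shifted by a genetic score, measured at an enrolment visit and a first
#' repeat visit. Statin users are split into the three strata the adjustment
#' machinery needs: never on statins, on statins from enrolment onward, and
#' on statins at the repeat visit only. On-statin measurements equal the
#' latent value times `cfg$statin_effect` times log-normal noise.
#'
#' @param ids Individual identifiers.
#' @param genetic_score Per-individual standardized score shifting the log
#'   biomarker by `prs_effect` per SD (use 0 shift for null biomarkers).
#' @param cfg A [synth_cohort_config()].
#' @param biomarker Name of the biomarker column tag.
#' @param prs_effect Log-scale effect per SD of `genetic_score`.
#' @param noise_sd SD of the multiplicative log-normal measurement noise.
#' @param sex Optional per-individual sex labels ("F"/"M"); defaults to "F".
#' @param seed Optional seed override (defaults to a stream of `cfg$seed`).
#' @return Data frame with one row per individual: `id`, `sex`, `biomarker`,
#'   `latent`, `value_enrol`, `value_repeat`, `statin_enrol`,
#'   `statin_repeat`, plus covariates `age`, `age_diff`, `deprivation`,
#'   `fasting_time`.
#' @export
gen_biomarkers <- function(ids, genetic_score, cfg,
                           biomarker = "biomarker",
                           prs_effect = 0,
                           noise_sd = 0.05,
                           sex = NULL,
                           seed = NULL) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  if (cfg$statin_effect <= 0) stop_param("statin_effect must be > 0")
  n <- length(ids)
  stopifnot(length(genetic_score) == n)
  sex <- sex %||% rep("F", n)
  with_seed(seed %||% child_seed(cfg$seed, 3L), {
    latent <- exp(log(1.5) + prs_effect * genetic_score +
                    stats::rnorm(n, sd = 0.3))
    u <- stats::runif(n)
    # strata: never / statin at enrolment onward / statin at repeat only
    statin_enrol <- u < cfg$statin_usage_rate / 2
    statin_repeat <- u < cfg$statin_usage_rate
    noise <- function() if (noise_sd > 0) stats::rlnorm(n, 0, noise_sd) else 1
    eff <- cfg$statin_effect
    value_enrol <- latent * ifelse(statin_enrol, eff, 1) * noise()
    value_repeat <- latent * ifelse(statin_repeat, eff, 1) * noise()
    data.frame(id = ids, sex = sex, biomarker = biomarker,
               latent = latent,
               value_enrol = value_enrol, value_repeat = value_repeat,
               statin_enrol = statin_enrol, statin_repeat = statin_repeat,
               age = round(stats::runif(n, 40, 69)),
               age_diff = round(stats::runif(n, 2, 6)),
               deprivation = stats::rnorm(n),
               fasting_time = stats::rpois(n, 4),
               stringsAsFactors = FALSE)
  })
}

#' Generate female-specific reproductive factors
#'
#' Draws menarche age, menopause age, menstrual cycle length, parity, age at
#' first live birth and first-child birth weight around realistic centres,
#' with an optional shift per SD of a genetic score and a configurable
#' fraction of out-of-range values to exercise the QC windows.
#'
#' @param ids Individual identifiers.
#' @param genetic_score Standardized per-individual score.
#' @param shift Named list/vector of per-SD shifts (default all 0). Names
#'   among menarche, menopause, cycle_length, parity, first_birth_age,
#'   birth_weight.
#' @param out_of_range Fraction of individuals given a menarche age outside
#'   the 8-20 QC window.
#' @param seed Integer seed.
#' @return Data frame with one row per individual and the six factors.
#' @export
gen_female_factors <- function(ids, genetic_score, shift = list(),
                               out_of_range = 0, seed = 1L) {
  n <- length(ids)
  stopifnot(length(genetic_score) == n)
  sh <- function(nm) if (!is.null(shift[[nm]])) shift[[nm]] else 0
  with_seed(seed, {
    menarche <- round(13 + sh("menarche") * genetic_score +
                        stats::rnorm(n, sd = 1.5))
    if (out_of_range > 0) {
      bad <- stats::runif(n) < out_of_range
      menarche[bad] <- sample(c(5L, 6L, 7L, 21L, 22L), sum(bad),
                              replace = TRUE)
    }
    menopause <- round(50 + sh("menopause") * genetic_score +
                         stats::rnorm(n, sd = 4))
    cycle_length <- round(28 + sh("cycle_length") * genetic_score +
                            stats::rnorm(n, sd = 3))
    parity <- stats::rpois(n, pmax(0.1, 1.8 + sh("parity") * genetic_score))
    first_birth_age <- round(26 + sh("first_birth_age") * genetic_score +
                               stats::rnorm(n, sd = 4))
    birth_weight <- 7.5 + sh("birth_weight") * genetic_score +
      stats::rnorm(n, sd = 1.2)
    data.frame(id = ids,
               menarche = menarche,
               menopause = menopause,
               cycle_length = cycle_length,
               parity = parity,
               first_birth_age = first_birth_age,
               birth_weight = round(birth_weight, 1),
               stringsAsFactors = FALSE)
  })
}

#' Generate paired exposure/outcome GWAS summary statistics
#'
#' Simulates `k_instruments` independent SNPs. True instrument effects on the
#' exposure have magnitudes uniform in `gamma_range` with random signs;
#' observed effects add sampling noise at the large-sample standard error
#' `1/sqrt(2 p (1-p) n)`. Outcome effects are `true_b * gamma + alpha +
#' noise`, with the pleiotropic `alpha` controlled by `pleiotropy_mode`, and
#' `n_outliers` SNPs receiving gross shifts of `outlier_shift` (alternating
#' sign).
#'
#' @param cfg A [synth_mr_config()].
#' @return List with `exposure` and `outcome` (`sumstats` objects) and
#'   `truth` (true_b, per-SNP gamma and alpha, outlier snp_ids).
#' @export
gen_two_sample_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "synth_mr_config"))
  with_seed(cfg$seed, {
    k <- cfg$k_instruments
    p <- stats::runif(k, 0.1, 0.9)
    gamma <- stats::runif(k, cfg$gamma_range[1], cfg$gamma_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    se_x <- 1 / sqrt(2 * p * (1 - p) * cfg$n_exposure)
    se_y <- 1 / sqrt(2 * p * (1 - p) * cfg$n_outcome)
    beta_x <- gamma + stats::rnorm(k, sd = se_x)
    # directional pleiotropy is defined relative to the exposure-increasing
    # allele (the orientation MR-Egger uses), so its sign tracks sign(gamma)
    alpha <- switch(cfg$pleiotropy_mode,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, cfg$pleiotropy_sd),
      directional = sign(gamma) *
        stats::rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      inside_violating = cfg$pleiotropy_sd * gamma / stats::sd(gamma) +
        stats::rnorm(k, 0, cfg$pleiotropy_sd / 2)
    )
    # gross outliers share one direction relative to the exposure-increasing
    # allele: a pleiotropic pathway biasing the slope coherently, the
    # regime outlier removal repairs
    outlier_idx <- integer(0)
    if (cfg$n_outliers > 0) {
      outlier_idx <- sample.int(k, cfg$n_outliers)
      alpha[outlier_idx] <- alpha[outlier_idx] +
        sign(gamma[outlier_idx]) * cfg$outlier_shift
    }
    beta_y <- cfg$true_b * gamma + alpha + stats::rnorm(k, sd = se_y)
    snp <- sprintf("rs%05d", seq_len(k))
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, k, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
    mk <- function(beta, se, n, trait) {
      sumstats(data.frame(
        snp_id = snp, chrom = as.character(1L + (seq_len(k) - 1L) %% 22L),
        pos = 10000L + 2000000L * ((seq_len(k) - 1L) %/% 22L),
        effect_allele = ea, other_allele = unname(oa), eaf = p,
        beta = beta, se = se,
        p = 2 * stats::pnorm(-abs(beta / se)),
        n = n, stringsAsFactors = FALSE), trait = trait)
    }
    list(exposure = mk(beta_x, se_x, cfg$n_exposure, "exposure"),
         outcome = mk(beta_y, se_y, cfg$n_outcome, "outcome"),
         truth = list(true_b = cfg$true_b, gamma = gamma, alpha = alpha,
                      outliers = snp[sort(outlier_idx)]))
  })
}
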