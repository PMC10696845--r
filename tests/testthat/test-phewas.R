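test_that("endometriosis case definition excludes N80.0-only individuals", {
  ids <- c("a", "b", "c", "d", "e")
  rec <- data.frame(id = c("a", "b", "b", "c", "d"),
                    icd10 = c("N80.0", "N80.0", "N80.1", "N80.4", "I10"))
  out <- define_endometriosis_cases(rec, ids)
  expect_equal(unname(out$case), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_setequal(out$sensitivity_ids, c("a", "d", "e"))
})

test_that("phecode table applies the minimum-count inclusion rule", {
  map <- load_phecode_map()
  ids <- sprintf("i%04d", 1:300)
  rec <- data.frame(
    id = c(ids[1:100], ids[1:99], ids[1]),
    icd10 = c(rep("I10", 100),       # phecode 401: 100 carriers, included
              rep("N92.0", 99),      # phecode 625: 99 carriers, excluded
              "N92.1"))              # second code for the same phecode/id
  out <- build_phecode_table(rec, map, ids, min_count = 100)
  expect_identical(colnames(out$table), "401")
  expect_equal(out$phecodes$n_cases, 100L)
  # the individual with two ICD10 codes mapping to one phecode counts once
  rec2 <- rbind(rec, data.frame(id = ids[100], icd10 = "N92.4"))
  out2 <- build_phecode_table(rec2, map, ids, min_count = 100)
  expect_setequal(colnames(out2$table), c("401", "625"))
  expect_equal(sum(out2$table[, "625"]), 100)
})

test_that("logistic PheWAS recovers a known odds ratio and flags degenerates", {
  set.seed(31)
  n <- 8000
  prs <- rnorm(n)
  covs <- data.frame(age = runif(n, 40, 70), PC1 = rnorm(n))
  logit <- qlogis(0.08) + log(1.3) * prs
  reps <- 25
  est <- vapply(seq_len(reps), function(i) {
    y <- rbinom(n, 1, plogis(logit))
    tab <- list(table = matrix(y, ncol = 1, dimnames = list(NULL, "x")),
                phecodes = data.frame(phecode = "x", category = "test"))
    phewas_logistic(prs, tab, covs)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - log(1.3)), 0.05)

  # all-control column: flagged, no estimate
  tab0 <- list(table = matrix(0L, n, 1, dimnames = list(NULL, "z")),
               phecodes = data.frame(phecode = "z", category = "test"))
  r0 <- phewas_logistic(prs, tab0, covs)
  expect_true(is.na(r0$estimate))
  expect_match(r0$flag, "single-class")
})

test_that("null phecodes reject at the nominal rate", {
  set.seed(32)
  n <- 2000
  reps <- 200
  pvals <- vapply(seq_len(reps), function(i) {
    prs <- rnorm(n)
    y <- rbinom(n, 1, 0.1)
    tab <- list(table = matrix(y, ncol = 1, dimnames = list(NULL, "x")),
                phecodes = data.frame(phecode = "x", category = "t"))
    phewas_logistic(prs, tab, data.frame(age = runif(n, 40, 70)))$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("statin correction factors are per-sex mean on/pre ratios", {
  vis <- data.frame(
    id = c("a", "b", "c", "d"), sex = c("F", "F", "F", "M"),
    biomarker = "ldl",
    value_enrol = c(2.0, 1.0, 1.0, 2.0),
    value_repeat = c(1.5, 0.7, 0.8, 1.0),
    statin_enrol = c(FALSE, FALSE, FALSE, FALSE),
    statin_repeat = c(TRUE, TRUE, TRUE, TRUE))
  out <- statin_correction_factors(vis)
  # single male ratio 0.5; female mean of (0.75, 0.7, 0.8) = 0.75
  expect_equal(out$factor[out$sex == "F"], 0.75)
  expect_equal(out$factor[out$sex == "M"], 0.5)

  # no qualifying individuals: factor undefined, reported not dropped
  vis$statin_enrol <- TRUE
  out2 <- statin_correction_factors(vis)
  expect_true(all(is.na(out2$factor)))
  expect_equal(out2$n, c(0L, 0L))
})

test_that("simulated statin effect is recovered as the correction factor", {
  cfg <- synth_cohort_config(n_individuals = 5000, statin_effect = 0.75,
                             statin_usage_rate = 0.6, seed = 33)
  ids <- sprintf("i%04d", 1:5000)
  vis <- gen_biomarkers(ids, rep(0, 5000), cfg, noise_sd = 0.05)
  out <- statin_correction_factors(vis)
  expect_lt(abs(out$factor - 0.75), 0.01)
})

test_that("statin flagging detects true effects and controls the null", {
  thr_traits <- 34
  cfg_eff <- synth_cohort_config(n_individuals = 2000, statin_effect = 0.6,
                                 statin_usage_rate = 0.6, seed = 34)
  ids <- sprintf("i%04d", 1:2000)
  flagged <- vapply(1:20, function(i) {
    vis <- gen_biomarkers(ids, rep(0, 2000), cfg_eff, noise_sd = 0.3,
                          seed = 1000 + i)
    flag_statin_affected(vis, n_traits = thr_traits)$flagged
  }, logical(1))
  expect_gt(mean(flagged), 0.95)

  # statin_effect = 1: flag rate at the Bonferroni-corrected null level
  cfg_null <- synth_cohort_config(n_individuals = 500, statin_effect = 1,
                                  statin_usage_rate = 0.6, seed = 35)
  idn <- sprintf("i%03d", 1:500)
  pvals <- vapply(1:300, function(i) {
    vis <- gen_biomarkers(idn, rep(0, 500), cfg_null, noise_sd = 0.3,
                          seed = 2000 + i)
    flag_statin_affected(vis, n_traits = thr_traits)$p
  }, numeric(1))
  expect_lt(mean(pvals < 0.05 / thr_traits), 0.02)
  # raw p-values roughly uniform under the null
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("biomarker adjustment divides only flagged on-statin values", {
  vis <- data.frame(
    id = c("a", "b", "c", "d"), sex = "F",
    biomarker = c("ldl", "ldl", "crp", "ldl"),
    value_enrol = c(1.5, 1.5, 1.5, 1.5), value_repeat = 1,
    statin_enrol = c(TRUE, FALSE, TRUE, TRUE),
    statin_repeat = TRUE)
  flags <- data.frame(sex = c("F", "F"), biomarker = c("ldl", "crp"),
                      flagged = c(TRUE, FALSE))
  factors <- data.frame(sex = c("F", "F"), biomarker = c("ldl", "crp"),
                        factor = c(0.75, 0.9))
  out <- adjust_biomarkers(vis, flags, factors)
  expect_equal(out$value_enrol, c(2.0, 1.5, 1.5, 2.0))
  expect_equal(out$value_repeat, vis$value_repeat)
})

test_that("adjustment with the true factor returns unbiased latent values", {
  cfg <- synth_cohort_config(n_individuals = 5000, statin_effect = 0.75,
                             statin_usage_rate = 0.6, seed = 36)
  ids <- sprintf("i%04d", 1:5000)
  vis <- gen_biomarkers(ids, rep(0, 5000), cfg, noise_sd = 0.05)
  factors <- statin_correction_factors(vis)
  flags <- data.frame(sex = "F", biomarker = "biomarker", flagged = TRUE)
  adj <- adjust_biomarkers(vis, flags, factors)
  on_statin <- adj$statin_enrol
  rel_err <- abs(mean(adj$value_enrol[on_statin] / adj$latent[on_statin]) - 1)
  expect_lt(rel_err, 0.01)
})

test_that("biomarker PheWAS recovers a log-scale effect per PRS SD", {
  set.seed(37)
  n <- 20000
  reps <- 30
  est <- vapply(seq_len(reps), function(i) {
    prs <- rnorm(n)
    y <- exp(log(1.5) + 0.014 * prs + rnorm(n, sd = 0.3))
    covs <- data.frame(fasting_time = rpois(n, 4), age = runif(n, 40, 70))
    phewas_biomarkers(prs, list(tg = y), covs)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.014), 0.002)

  expect_error(
    phewas_biomarkers(rnorm(10), list(x = c(-1, runif(9))),
                      data.frame(age = runif(10))),
    "nonpositive")
})

test_that("female-factor QC applies the plausibility windows exactly", {
  ff <- data.frame(id = sprintf("i%02d", 1:8),
                   menarche = c(7, 8, 20, 21, 13, 13, 13, 13),
                   menopause = c(39, 40, 63, 64, 50, 50, 50, 50),
                   cycle_length = c(21, 22, 36, 37, 28, 28, 28, 28),
                   parity = c(0, 1, 2, 3, 4, 7, 2, 1),
                   first_birth_age = c(13, 14, 43, 44, 25, 25, 25, 25),
                   birth_weight = c(2.9, 3, 12, 12.1, 7.5, 7.5, 7.5, 7.5))
  out <- female_factor_qc(ff)
  expect_equal(is.na(out$menarche), c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 4)))
  expect_equal(is.na(out$menopause), c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 4)))
  expect_equal(is.na(out$cycle_length),
               c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 4)))
  expect_equal(is.na(out$first_birth_age),
               c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 4)))
  expect_equal(is.na(out$birth_weight),
               c(TRUE, FALSE, FALSE, TRUE, rep(FALSE, 4)))
  # parity 4 and 7 collapse into the single "4+" category
  expect_equal(as.character(out$parity),
               c("0", "1", "2", "3", "4+", "4+", "2", "1"))
  expect_true(is.ordered(out$parity))
})

test_that("repeated visits use last value for parity, first for the rest", {
  ff <- data.frame(id = c("a", "a", "b"), visit = c(1, 2, 1),
                   menarche = c(12, 14, 13), menopause = c(50, 51, 49),
                   cycle_length = c(28, 30, 27), parity = c(1, 3, 2),
                   first_birth_age = c(24, 26, 30),
                   birth_weight = c(7, 8, 6))
  out <- female_factor_qc(ff)
  a <- out[out$id == "a", ]
  expect_equal(a$menarche, 12)       # first recorded value
  expect_equal(as.character(a$parity), "3")  # last recorded value
})

test_that("inverse-rank-normal transform is symmetric and rank-preserving", {
  set.seed(38)
  x <- rexp(2000)  # heavily skewed input
  z <- irnt(x)
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skew), 0.01)
  expect_equal(order(x), order(z))
  # ties share the average rank, hence the same transformed value
  zt <- irnt(c(1, 2, 2, 3))
  expect_equal(zt[2], zt[3])
  expect_equal(irnt(c(1, NA, 2))[2], NA_real_)
})

test_that("female-factor PheWAS fits linear and ordinal models", {
  set.seed(39)
  n <- 6000
  prs <- rnorm(n)
  # ordinal cycle length shifted by -0.3 latent units per PRS SD
  lat <- -0.3 * prs + rnorm(n)
  cyc <- cut(lat, breaks = c(-Inf, -1, 0, 1, Inf), labels = 22:25,
             ordered_result = TRUE)
  ff <- data.frame(id = seq_len(n), menarche = round(13 - 0.1 * prs +
                                                       rnorm(n, sd = 1.5)))
  ff$cycle_length <- as.numeric(as.character(cyc))
  ffq <- female_factor_qc(data.frame(
    ff, menopause = 50, parity = 2, first_birth_age = 26, birth_weight = 7))
  covs <- data.frame(PC1 = rnorm(n))
  res <- phewas_female_factors(prs, ffq, covs,
                               models = c(menarche = "linear",
                                          cycle_length = "ordinal"))
  lin <- res[res$trait == "menarche", ]
  ord <- res[res$trait == "cycle_length", ]
  expect_equal(lin$model, "linear")
  expect_lt(lin$estimate, 0)
  expect_lt(lin$p, 1e-4)
  expect_equal(ord$model, "ordinal")
  # proportional-odds estimate tracks the latent shift (logit scale ~ 1.7x)
  expect_lt(ord$estimate, -0.3)
  expect_lt(ord$p, 1e-6)
  # p-values computed from the normal tail of the t-value
  expect_equal(ord$p, 2 * pnorm(-abs(ord$estimate / ord$se)))

  ffq$cycle_length <- 28
  expect_error(
    phewas_female_factors(prs, ffq, covs,
                          models = c(cycle_length = "ordinal")),
    "< 2 levels")
})

test_that("Bonferroni thresholds divide alpha by the trait count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})
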