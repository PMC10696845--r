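test_that("instrument selection applies the strict threshold and clumping", {
  ss <- make_sumstats(k = 4,
                      chrom = c("1", "1", "1", "2"),
                      pos = c(1e6, 1.5e6, 5e6, 1e6),
                      beta = c(0.10, 0.08, 0.09, 0.12),
                      se = rep(0.01, 4),
                      p = c(1e-20, 1e-10, 5e-8, 1e-30))
  # p = 5e-8 exactly is excluded (strict <)
  kept <- select_instruments(ss)
  expect_false("rs003" %in% kept)
  # two significant SNPs 500 kb apart, no LD info: only the lower-p one
  expect_true("rs001" %in% kept)
  expect_false("rs002" %in% kept)
  expect_true("rs004" %in% kept)

  # with LD info, an unlinked nearby pair is both retained
  ld <- data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.0001)
  kept_ld <- select_instruments(ss, ld = ld)
  expect_true(all(c("rs001", "rs002") %in% kept_ld))

  # synthetic unlinked instruments: all retained (distance-separated)
  sim <- gen_two_sample_sumstats(synth_mr_config(
    k_instruments = 50, gamma_range = c(0.1, 0.2), seed = 50))
  expect_length(select_instruments(sim$exposure), 50)

  expect_error(select_instruments(make_sumstats(k = 2, p = c(0.5, 0.9))),
               "no instruments")
})

test_that("harmonization aligns alleles and drops ambiguous palindromes", {
  ex <- make_sumstats(k = 3, effect_allele = c("A", "C", "A"),
                      other_allele = c("G", "G", "T"),
                      eaf = c(0.3, 0.3, 0.50),
                      beta = c(0.1, 0.1, 0.1))
  ou_df <- ex$snps
  ou_df$effect_allele <- c("G", "C", "A")  # rs001 swapped
  ou_df$other_allele <- c("A", "G", "T")
  ou_df$beta <- c(0.05, 0.05, 0.05)
  ou_df$eaf <- c(0.7, 0.3, 0.5)
  ou <- sumstats(ou_df, trait = "outcome")
  h <- harmonize(ex, ou)
  # A/T palindrome at eaf 0.50 dropped
  expect_false("rs003" %in% h$snp_id)
  # swapped outcome beta sign-flipped
  expect_equal(h$beta_outcome[h$snp_id == "rs001"], -0.05)
  expect_equal(h$beta_outcome[h$snp_id == "rs002"], 0.05)
  expect_equal(attr(h, "report")$n_flipped, 1)

  # already-aligned input: identity, zero report actions
  h2 <- harmonize(ex, ex)
  expect_equal(attr(h2, "report")$n_flipped, 0)
  expect_length(attr(h2, "report")$dropped_irreconcilable, 0)
  expect_equal(h2$beta_outcome, h2$beta_exposure)
})

test_that("F-statistics filter weak instruments, invariant to sign", {
  mri <- make_mr_input(beta_exposure = c(0.1, 0.01),
                       beta_outcome = c(0.02, 0.002),
                       se_exposure = c(0.01, 0.01))
  out <- f_statistics(mri)
  expect_identical(out$snp_id, "rs001")
  expect_equal(out$f_stat, 100)
  expect_identical(attr(out, "report")$removed, "rs002")
  # squaring makes F sign-invariant
  mri_neg <- make_mr_input(beta_exposure = c(-0.1, -0.01),
                           beta_outcome = c(0.02, 0.002),
                           se_exposure = c(0.01, 0.01))
  expect_equal(attr(f_statistics(mri_neg), "report")$f,
               attr(out, "report")$f)
})

test_that("Steiger filter retains instruments stronger for the exposure", {
  # r2 = z^2 / (z^2 + n - 2) decreases in n at fixed z: equal z with the
  # larger exposure sample size means LESS exposure variance explained,
  # so the SNP is removed
  mri <- make_mr_input(beta_exposure = 0.1, beta_outcome = 0.1,
                       se_exposure = 0.01, se_outcome = 0.01,
                       n_exposure = 200000, n_outcome = 100000)
  expect_error(steiger_filter(mri), "no instruments")

  # boundary: identical z and n gives r2_exp == r2_out, removed (strict)
  mri_eq <- make_mr_input(beta_exposure = c(0.1, 0.3),
                          beta_outcome = c(0.1, 0.01),
                          se_exposure = c(0.01, 0.01),
                          se_outcome = c(0.01, 0.01))
  out <- steiger_filter(mri_eq)
  expect_identical(out$snp_id, "rs002")

  # exposure associations simulated 10x stronger: everything retained
  sim <- simulate_mr_input(seed = 51)
  expect_equal(nrow(steiger_filter(sim)), nrow(sim))
})

test_that("Wald ratio matches the closed form and rejects zero exposure", {
  r <- wald_ratio(0.1, -0.02, 0.005)
  expect_equal(r$b, -0.2)
  expect_equal(r$se, 0.05)
  expect_equal(r$p, 2 * pnorm(-abs(-0.2 / 0.05)))
  expect_equal(wald_ratio(0.1, 0, 0.005)$b, 0)
  expect_error(wald_ratio(0, 0.1, 0.005), "undefined")
})

test_that("IVW reduces to the Wald ratio at k = 1 and computes Q", {
  mri1 <- make_mr_input(beta_exposure = 0.1, beta_outcome = -0.02,
                        se_outcome = 0.005)
  r <- ivw(mri1)
  w <- wald_ratio(0.1, -0.02, 0.005)
  expect_equal(r$b, w$b)
  expect_equal(r$se, w$se)
  expect_equal(r$p, w$p)

  # all ratios identical: Q = 0, Q_p = 1, no inflation
  mri <- make_mr_input(beta_exposure = c(0.1, 0.2, 0.4),
                       beta_outcome = c(0.05, 0.10, 0.20),
                       se_outcome = c(0.01, 0.01, 0.01))
  r2 <- ivw(mri)
  expect_equal(r2$b, 0.5)
  expect_equal(r2$Q, 0)
  expect_equal(r2$Q_p, 1)
  expect_equal(r2$Q_df, 2)
})

test_that("MR estimators are sign-coherent in the exposure betas", {
  mri <- simulate_mr_input(seed = 52)
  neg <- as.data.frame(mri)
  neg$beta_exposure <- -neg$beta_exposure
  neg <- mr_input(neg)
  expect_equal(ivw(neg)$b, -ivw(mri)$b)
  expect_equal(mr_egger(neg)$b, -mr_egger(mri)$b)
  expect_equal(weighted_median(neg, seed = 1)$b,
               -weighted_median(mri, seed = 1)$b)
})

test_that("Egger fits the exact line on collinear points through the origin", {
  mri <- make_mr_input(beta_exposure = c(0.1, 0.2, 0.4),
                       beta_outcome = c(-0.02, -0.04, -0.08),
                       se_outcome = c(0.01, 0.01, 0.01))
  r <- mr_egger(mri)
  expect_equal(r$b, -0.2)
  expect_equal(r$egger_intercept, 0, tolerance = 1e-12)
  expect_error(mr_egger(make_mr_input(beta_exposure = c(0.1, 0.2),
                                      beta_outcome = c(0.1, 0.2))),
               "k >= 3")
})

test_that("Egger intercept recovers directional pleiotropy", {
  reps <- 120
  ints <- vapply(seq_len(reps), function(i) {
    mri <- simulate_mr_input(seed = 5200 + i, pleiotropy_mode = "directional",
                             pleiotropy_mean = 0.01, k_instruments = 50)
    mr_egger(mri)$egger_intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.01), 0.003)
})

test_that("Egger intercept test holds its size under no pleiotropy", {
  reps <- 200
  pvals <- vapply(seq_len(reps), function(i) {
    mri <- simulate_mr_input(seed = 5600 + i, k_instruments = 30)
    mr_egger(mri)$egger_intercept_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("weighted median interpolates the 50% weight point", {
  # equal weights, odd k: the middle ratio
  mri <- make_mr_input(beta_exposure = c(1, 1, 1),
                       beta_outcome = c(0.1, 0.3, 0.9),
                       se_outcome = c(0.01, 0.01, 0.01))
  r <- weighted_median(mri, n_boot = 50, seed = 1)
  expect_equal(r$b, 0.3)
  # bootstrap with the same seed reproduces the SE exactly
  r2 <- weighted_median(mri, n_boot = 50, seed = 1)
  expect_identical(r$se, r2$se)
  expect_false(identical(weighted_median(mri, n_boot = 50, seed = 2)$se,
                         r$se))
})

test_that("weighted median resists 40% balanced gross pleiotropy", {
  reps <- 100
  est <- vapply(seq_len(reps), function(i) {
    mri <- simulate_mr_input(seed = 6000 + i, true_b = -0.2,
                             k_instruments = 30)
    # contaminate 40% of instruments with balanced gross direct effects
    bad <- 1:12
    df <- as.data.frame(mri)
    df$beta_outcome[bad] <- df$beta_outcome[bad] +
      rep(c(0.05, -0.05), 6)
    weighted_median(mr_input(df), n_boot = 100, seed = i)$b
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.2)), 0.03)
})

test_that("estimators agree in the noiseless pleiotropy-free limit", {
  sim <- gen_two_sample_sumstats(synth_mr_config(
    true_b = -0.2, n_exposure = 2000000000, n_outcome = 2000000000,
    seed = 53))
  mri <- harmonize(sim$exposure, sim$outcome)
  b_ivw <- ivw(mri)$b
  b_egg <- mr_egger(mri)$b
  b_wm <- weighted_median(mri, seed = 1)$b
  expect_lt(abs(b_ivw - b_egg), 0.01)
  expect_lt(abs(b_ivw - b_wm), 0.01)
  expect_lt(abs(b_ivw - (-0.2)), 0.01)
})

test_that("leave-one-out flags the influential outlier", {
  mri <- simulate_mr_input(seed = 54, k_instruments = 20, true_b = -0.2,
                           n_outliers = 1, outlier_shift = 0.2)
  sim <- gen_two_sample_sumstats(synth_mr_config(
    seed = 54, k_instruments = 20, true_b = -0.2, n_outliers = 1,
    outlier_shift = 0.2))
  loo <- leave_one_out(mri)
  full_b <- attr(loo, "full")$b
  shifts <- abs(loo$b - full_b)
  expect_equal(loo$snp_id[which.max(shifts)], sim$truth$outliers)

  # homogeneous input: every omission stays close to the full estimate
  mri_h <- simulate_mr_input(seed = 55, k_instruments = 30, true_b = -0.2)
  loo_h <- leave_one_out(mri_h)
  expect_lt(max(abs(loo_h$b - attr(loo_h, "full")$b)), 0.05)

  # k = 2 reduces to a pair of Wald ratios
  mri2 <- make_mr_input(beta_exposure = c(0.1, 0.2),
                        beta_outcome = c(0.02, 0.05),
                        se_outcome = c(0.01, 0.01))
  loo2 <- leave_one_out(mri2)
  expect_equal(loo2$b, c(0.05 / 0.2, 0.02 / 0.1))
})

test_that("MR-PRESSO is seeded, reduces to IVW without outliers, needs k >= 4", {
  mri <- simulate_mr_input(seed = 56, k_instruments = 15, true_b = -0.2)
  p1 <- mr_presso(mri, n_sim = 200, seed = 9)
  p2 <- mr_presso(mri, n_sim = 200, seed = 9)
  expect_identical(p1$outliers, p2$outliers)
  expect_identical(p1$global_p, p2$global_p)
  # no outliers detected: adjusted estimate equals plain IVW
  expect_length(p1$outliers, 0)
  expect_equal(p1$outlier_adjusted$b, ivw(mri)$b)
  expect_error(mr_presso(make_mr_input(beta_exposure = c(1, 1, 1),
                                       beta_outcome = c(1, 1, 1))),
               "k >= 4")
})

test_that("MR-PRESSO flags planted outliers and repairs the estimate", {
  mri <- simulate_mr_input(seed = 57, k_instruments = 30, true_b = -0.2,
                           n_outliers = 2)
  sim <- gen_two_sample_sumstats(synth_mr_config(
    seed = 57, k_instruments = 30, true_b = -0.2, n_outliers = 2))
  pr <- mr_presso(mri, n_sim = 500, seed = 11)
  expect_true(all(intersect(sim$truth$outliers, mri$snp_id) %in%
                    pr$outliers))
  expect_lt(pr$global_p, 0.05)
  expect_lt(abs(pr$outlier_adjusted$b - (-0.2)), abs(pr$raw$b - (-0.2)))
  expect_equal(pr$outlier_adjusted$outliers_removed, length(pr$outliers))
})

test_that("multivariable MR reduces to IVW and separates exposures", {
  mri <- simulate_mr_input(seed = 58)
  single <- mvmr(matrix(mri$beta_exposure, ncol = 1,
                        dimnames = list(NULL, "x1")),
                 mri$beta_outcome, mri$se_outcome)
  expect_equal(single$b, ivw(mri)$b)

  # two correlated exposures, only the first causal
  reps <- 100
  est <- t(vapply(seq_len(reps), function(i) {
    set.seed(7000 + i)
    k <- 40
    g1 <- runif(k, 0.02, 0.06) * sample(c(-1, 1), k, TRUE)
    g2 <- 0.6 * g1 + 0.04 * rnorm(k)  # correlated instrument effects
    se_y <- rep(0.004, k)
    by <- -0.2 * g1 + 0 * g2 + rnorm(k, sd = se_y)
    fit <- mvmr(cbind(x1 = g1, x2 = g2), by, se_y)
    fit$b
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - (-0.2)), 0.01)
  expect_lt(abs(mean(est[, 2])), 0.01)

  X <- cbind(x1 = mri$beta_exposure, x2 = mri$beta_exposure)
  expect_error(mvmr(X, mri$beta_outcome, mri$se_outcome),
               "rank-deficient.*x2")
})

test_that("group-wise FDR matches the naive BH oracle and respects groups", {
  res <- rbind(
    mr_result_rows <- data.frame(
      method = rep(c("ivw", "egger"), each = 3),
      direction = "exposure->outcome",
      p = c(0.01, 0.02, 0.03, 0.5, 0.01, 0.9),
      p_adjusted = NA_real_))
  out <- fdr_within_groups(res)
  expect_equal(out$p_adjusted[1:3], c(0.03, 0.03, 0.03))
  # groups adjusted independently
  expect_equal(out$p_adjusted[4:6], p.adjust(c(0.5, 0.01, 0.9), "BH"))

  single <- data.frame(method = "ivw", direction = "d", p = 0.2,
                       p_adjusted = NA_real_)
  expect_equal(fdr_within_groups(single)$p_adjusted, 0.2)

  set.seed(59)
  for (i in 1:25) {
    p <- runif(sample(3:30, 1))
    df <- data.frame(method = "ivw", direction = "d", p = p,
                     p_adjusted = NA_real_)
    adj <- fdr_within_groups(df)$p_adjusted
    expect_equal(adj, bh_naive(p))
    # monotone nondecreasing in raw p within group
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
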