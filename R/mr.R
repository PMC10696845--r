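# Two-sample Mendelian randomisation: instrument selection, harmonization,
# directionality filtering, estimation and sensitivity analyses.

# Build a one-row MR result data frame with the standard columns.
mr_result <- function(method, b, se, p, k, Q = NA_real_, Q_df = NA_real_,
                      Q_p = NA_real_, intercept = NA_real_,
                      intercept_p = NA_real_, outliers_removed = NA_integer_,
                      direction = "exposure->outcome") {
  data.frame(method = method, b = b, se = se, p = p, p_adjusted = NA_real_,
             k = k, Q = Q, Q_df = Q_df, Q_p = Q_p,
             egger_intercept = intercept, egger_intercept_p = intercept_p,
             outliers_removed = outliers_removed, direction = direction,
             stringsAsFactors = FALSE)
}

#' Construct a harmonized MR input set
#'
#' @param snps Data frame with columns `snp_id`, `beta_exposure`,
#'   `se_exposure`, `p_exposure`, `n_exposure`, `beta_outcome`,
#'   `se_outcome`, `p_outcome`, `n_outcome`, `eaf`.
#' @return An object of class `mr_input`.
#' @export
mr_input <- function(snps) {
  req <- c("snp_id", "beta_exposure", "se_exposure", "p_exposure",
           "n_exposure", "beta_outcome", "se_outcome", "p_outcome",
           "n_outcome", "eaf")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols) > 0) {
    stop(sprintf("mr_input missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(snps) < 1) stop_param("mr_input needs k >= 1 SNPs")
  if (any(snps$se_exposure <= 0) || any(snps$se_outcome <= 0)) {
    stop_param("all standard errors must be > 0")
  }
  rownames(snps) <- NULL
  structure(snps, class = c("mr_input", "data.frame"))
}

#' Select independent genome-wide-significant instruments
#'
#' SNPs with p strictly below `p_max` are clumped greedily in p-value
#' order: a SNP is kept unless it lies within the clumping window of an
#' already-kept SNP and (when LD information is supplied) exceeds the r2
#' threshold. With LD information the window is 10 Mb and r2 > 0.001
#' removes; without it, a distance-only rule removes anything within 1 Mb
#' of a kept SNP on the same chromosome.
#'
#' @param ss A QC'd `sumstats` object.
#' @param p_max Significance threshold (strict <).
#' @param ld Optional data frame of pairwise LD: columns `snp_a`, `snp_b`,
#'   `r2`.
#' @param window_kb Clumping window (defaults depend on `ld`).
#' @param r2_max LD threshold used when `ld` is supplied.
#' @return Character vector of instrument snp_ids.
#' @export
select_instruments <- function(ss, p_max = 5e-8, ld = NULL,
                               window_kb = if (is.null(ld)) 1000 else 10000,
                               r2_max = 0.001) {
  stopifnot(inherits(ss, "sumstats"))
  df <- ss$snps[ss$snps$p < p_max, , drop = FALSE]
  if (nrow(df) == 0) stop_param("no instruments at p < %g", p_max)
  df <- df[order(df$p), , drop = FALSE]
  ld_r2 <- function(a, b) {
    if (is.null(ld)) return(1)  # distance-only: treat as linked
    hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
    if (any(hit)) max(ld$r2[hit]) else 0
  }
  kept <- character(0)
  kept_chrom <- character(0)
  kept_pos <- numeric(0)
  for (i in seq_len(nrow(df))) {
    near <- kept_chrom == df$chrom[i] &
      abs(kept_pos - df$pos[i]) <= window_kb * 1000
    linked <- FALSE
    for (j in which(near)) {
      if (ld_r2(df$snp_id[i], kept[j]) > r2_max) { linked <- TRUE; break }
    }
    if (!linked) {
      kept <- c(kept, df$snp_id[i])
      kept_chrom <- c(kept_chrom, df$chrom[i])
      kept_pos <- c(kept_pos, df$pos[i])
    }
  }
  kept
}

#' Harmonize exposure and outcome summary statistics
#'
#' Outcome records are aligned to the exposure effect allele: swapped
#' alleles flip the outcome beta and frequency, strand flips are resolved
#' via the complement, and irreconcilable alleles are dropped. Palindromic
#' SNPs (A/T or C/G) whose exposure frequency falls inside the ambiguity
#' window are dropped, since strand cannot be resolved for them.
#'
#' @param exposure,outcome `sumstats` objects sharing rsIDs.
#' @param snps Optional snp_id subset (e.g. from [select_instruments()]).
#' @param palindrome_eaf_window Frequency window for dropping palindromic
#'   SNPs.
#' @return An `mr_input`; attribute `report` counts flips and drops.
#' @export
harmonize <- function(exposure, outcome, snps = NULL,
                      palindrome_eaf_window = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$snps
  if (!is.null(snps)) ex <- ex[ex$snp_id %in% snps, , drop = FALSE]
  shared <- intersect(ex$snp_id, outcome$snps$snp_id)
  ex <- ex[ex$snp_id %in% shared, , drop = FALSE]
  ou <- outcome$snps[outcome$snps$snp_id %in% shared, , drop = FALSE]
  ou <- align_alleles(ou, ex$snp_id, ex$effect_allele, ex$other_allele)
  ex <- ex[match(ou$snp_id, ex$snp_id), , drop = FALSE]
  pal <- (ex$effect_allele == "A" & ex$other_allele == "T") |
    (ex$effect_allele == "T" & ex$other_allele == "A") |
    (ex$effect_allele == "C" & ex$other_allele == "G") |
    (ex$effect_allele == "G" & ex$other_allele == "C")
  ambiguous <- pal & !is.na(ex$eaf) &
    ex$eaf > palindrome_eaf_window[1] & ex$eaf < palindrome_eaf_window[2]
  keep <- !ambiguous
  out <- mr_input(data.frame(
    snp_id = ex$snp_id[keep],
    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
    p_exposure = ex$p[keep], n_exposure = ex$n[keep],
    beta_outcome = ou$beta[keep], se_outcome = ou$se[keep],
    p_outcome = ou$p[keep], n_outcome = ou$n[keep],
    eaf = ex$eaf[keep], stringsAsFactors = FALSE))
  attr(out, "report") <- list(
    n_shared = length(shared),
    n_flipped = attr(ou, "n_flipped"),
    dropped_irreconcilable = attr(ou, "dropped"),
    dropped_palindromic = ex$snp_id[ambiguous],
    n_out = nrow(out))
  out
}

#' Instrument-strength F-statistics
#'
#' Per SNP, F = (beta_exposure / se_exposure)^2; SNPs at or below `f_min`
#' are removed (the conventional weak-instrument cut is F > 10).
#'
#' @param mri An `mr_input`.
#' @param f_min Minimum F (strictly greater retained).
#' @return Filtered `mr_input` with column `f_stat`; attribute `report`
#'   lists removed SNPs.
#' @export
f_statistics <- function(mri, f_min = 10) {
  stopifnot(inherits(mri, "mr_input"))
  f <- (mri$beta_exposure / mri$se_exposure)^2
  keep <- f > f_min
  out <- as.data.frame(mri)[keep, , drop = FALSE]
  out$f_stat <- f[keep]
  if (nrow(out) == 0) stop_param("no instruments with F > %g", f_min)
  out <- mr_input(out)
  attr(out, "report") <- list(removed = mri$snp_id[!keep], f = f)
  out
}

#' Steiger directionality filter
#'
#' Per SNP the variance explained in each trait is approximated from the z
#' statistic and the sample size, r2 = z^2 / (z^2 + n - 2); a SNP is
#' retained only when it explains strictly more variance in the exposure
#' than in the outcome, orienting the instrument set toward the assumed
#' causal direction.
#'
#' @param mri An `mr_input` with per-SNP sample sizes for both traits.
#' @return Filtered `mr_input` with columns `r2_exposure`, `r2_outcome`;
#'   attribute `report` lists removed SNPs.
#' @export
steiger_filter <- function(mri) {
  stopifnot(inherits(mri, "mr_input"))
  if (any(mri$n_exposure <= 2 | mri$n_outcome <= 2)) {
    stop_param("Steiger filter requires n > 2 for both traits")
  }
  r2_of <- function(beta, se, n) {
    z2 <- (beta / se)^2
    z2 / (z2 + n - 2)
  }
  r2_exp <- r2_of(mri$beta_exposure, mri$se_exposure, mri$n_exposure)
  r2_out <- r2_of(mri$beta_outcome, mri$se_outcome, mri$n_outcome)
  keep <- r2_exp > r2_out
  out <- as.data.frame(mri)[keep, , drop = FALSE]
  out$r2_exposure <- r2_exp[keep]
  out$r2_outcome <- r2_out[keep]
  if (nrow(out) == 0) stop_param("no instruments pass the Steiger filter")
  out <- mr_input(out)
  attr(out, "report") <- list(removed = mri$snp_id[!keep],
                              r2_exposure = r2_exp, r2_outcome = r2_out)
  out
}

#' Wald ratio for a single instrument
#'
#' b = beta_outcome / beta_exposure with the first-order standard error
#' |se_outcome / beta_exposure| and a normal p-value.
#'
#' @param beta_exposure,beta_outcome,se_outcome Scalars (or an `mr_input`
#'   row passed via [ivw()] with k = 1).
#' @param direction Direction label for the result row.
#' @return One-row MR result data frame.
#' @export
wald_ratio <- function(beta_exposure, beta_outcome, se_outcome,
                       direction = "exposure->outcome") {
  if (beta_exposure == 0) stop_param("Wald ratio undefined for beta_exposure = 0")
  b <- beta_outcome / beta_exposure
  se <- abs(se_outcome / beta_exposure)
  mr_result("wald", b, se, 2 * stats::pnorm(-abs(b / se)), 1L,
            direction = direction)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect combination of per-SNP Wald ratios: b = sum(w bx by) /
#' sum(w bx^2) with w = 1/se_outcome^2, equivalent to weighted least
#' squares of the outcome betas on the exposure betas through the origin.
#' Cochran's Q is computed on the ratio scale; when Q/(k-1) exceeds 1 the
#' standard error is inflated by sqrt(Q/(k-1)) (multiplicative
#' random-effects model), matching the convention of reporting
#' heterogeneity-robust significance.
#'
#' @param mri An `mr_input` (k >= 1).
#' @param direction Direction label.
#' @return One-row MR result data frame with Q statistics.
#' @export
ivw <- function(mri, direction = "exposure->outcome") {
  stopifnot(inherits(mri, "mr_input"))
  k <- nrow(mri)
  bx <- mri$beta_exposure
  by <- mri$beta_outcome
  w <- 1 / mri$se_outcome^2
  b <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  if (k == 1) {
    res <- wald_ratio(bx, by, mri$se_outcome, direction)
    res$method <- "ivw"
    return(res)
  }
  ratio <- by / bx
  w_ratio <- (bx / mri$se_outcome)^2
  Q <- sum(w_ratio * (ratio - b)^2)
  Q_df <- k - 1
  Q_p <- stats::pchisq(Q, Q_df, lower.tail = FALSE)
  if (Q / Q_df > 1) se <- se * sqrt(Q / Q_df)
  mr_result("ivw", b, se, 2 * stats::pnorm(-abs(b / se)), k,
            Q = Q, Q_df = Q_df, Q_p = Q_p, direction = direction)
}

#' MR-Egger regression
#'
#' SNPs are oriented so all exposure betas are positive (both betas
#' flipped), then the outcome betas are regressed on the exposure betas
#' with an intercept, weighted by 1/se_outcome^2. The slope is the causal
#' estimate; a non-zero intercept indicates directional pleiotropy.
#' Standard errors use the multiplicative random-effects convention (model
#' sigma not allowed below 1) and p-values come from the t distribution
#' with k - 2 df.
#'
#' @param mri An `mr_input` with k >= 3.
#' @param direction Direction label.
#' @return One-row MR result data frame with intercept test.
#' @export
mr_egger <- function(mri, direction = "exposure->outcome") {
  stopifnot(inherits(mri, "mr_input"))
  k <- nrow(mri)
  if (k < 3) stop_param("MR-Egger requires k >= 3 instruments")
  flip <- sign(mri$beta_exposure)
  flip[flip == 0] <- 1
  bx <- mri$beta_exposure * flip
  by <- mri$beta_outcome * flip
  w <- 1 / mri$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  cf <- sm$coefficients
  scale <- max(1, sm$sigma) / sm$sigma  # never report below fixed-effect SE
  b <- cf["bx", 1]
  se_b <- cf["bx", 2] * scale
  a <- cf["(Intercept)", 1]
  se_a <- cf["(Intercept)", 2] * scale
  mr_result("egger", b, se_b, 2 * stats::pt(-abs(b / se_b), k - 2), k,
            intercept = a,
            intercept_p = 2 * stats::pt(-abs(a / se_a), k - 2),
            direction = direction)
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# cumulative weight function at 0.5 (standard construction).
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(x[1])
  if (0.5 >= cum[length(cum)]) return(x[length(x)])
  below <- max(which(cum < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median MR estimate
#'
#' Per-SNP Wald ratios are combined by the weighted median with
#' inverse-variance weights (first-order ratio variances); the estimate is
#' consistent when at least half the weight comes from valid instruments.
#' The standard error comes from a seeded parametric bootstrap of the
#' per-SNP betas.
#'
#' @param mri An `mr_input` with k >= 3.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param direction Direction label.
#' @return One-row MR result data frame.
#' @export
weighted_median <- function(mri, n_boot = 1000, seed = 1L,
                            direction = "exposure->outcome") {
  stopifnot(inherits(mri, "mr_input"))
  k <- nrow(mri)
  if (k < 3) stop_param("weighted median requires k >= 3 instruments")
  ratio <- mri$beta_outcome / mri$beta_exposure
  w <- (mri$beta_exposure / mri$se_outcome)^2  # 1 / first-order ratio var
  b <- weighted_median_point(ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, mri$beta_exposure, mri$se_exposure)
      by <- stats::rnorm(k, mri$beta_outcome, mri$se_outcome)
      weighted_median_point(by / bx, (bx / mri$se_outcome)^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_result("weighted_median", b, se, 2 * stats::pnorm(-abs(b / se)), k,
            direction = direction)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate k times, each omitting one SNP, and flags any
#' omission that changes the significance verdict at `alpha` relative to
#' the full-set estimate.
#'
#' @param mri An `mr_input` with k >= 2.
#' @param alpha Significance level for the verdict flag.
#' @return Data frame with one row per omitted SNP (snp_id, b, se, p,
#'   verdict_changed) plus the full estimate as attribute `full`.
#' @export
leave_one_out <- function(mri, alpha = 0.05) {
  stopifnot(inherits(mri, "mr_input"))
  k <- nrow(mri)
  if (k < 2) stop_param("leave-one-out requires k >= 2")
  full <- ivw(mri)
  rows <- lapply(seq_len(k), function(j) {
    sub <- ivw(mr_input(as.data.frame(mri)[-j, , drop = FALSE]))
    data.frame(snp_id = mri$snp_id[j], b = sub$b, se = sub$se, p = sub$p,
               verdict_changed = (sub$p < alpha) != (full$p < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

# Fixed-effect IVW slope (no Q machinery) used inside MR-PRESSO.
ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The global test compares the observed weighted residual sum of squares
#' (each SNP's outcome beta against its leave-one-out IVW prediction) to
#' `n_sim` parametric simulations under the fitted no-pleiotropy model.
#' When the global test is significant, each SNP's squared residual is
#' compared to its simulated distribution (Bonferroni over k) to flag
#' outliers; the IVW estimate is then refit without them. The distortion
#' test compares the observed raw-vs-adjusted change in the estimate to
#' the distribution obtained by removing random SNP subsets of the same
#' size.
#'
#' @param mri An `mr_input` with k >= 4.
#' @param n_sim Number of parametric simulations.
#' @param outlier_alpha Significance level for global and outlier tests.
#' @param seed Simulation seed.
#' @param direction Direction label.
#' @return List with `raw` and `outlier_adjusted` result rows, `outliers`
#'   (snp_ids), `global_rss`, `global_p`, `outlier_p` (per SNP) and
#'   `distortion_p`.
#' @export
mr_presso <- function(mri, n_sim = 1000, outlier_alpha = 0.05, seed = 1L,
                      direction = "exposure->outcome") {
  stopifnot(inherits(mri, "mr_input"))
  k <- nrow(mri)
  if (k < 4) stop_param("MR-PRESSO requires k >= 4 instruments")
  bx <- mri$beta_exposure
  by <- mri$beta_outcome
  sx <- mri$se_exposure
  sy <- mri$se_outcome
  w <- 1 / sy^2

  loo_slopes <- function(bx, by, w) {
    num <- sum(w * bx * by)
    den <- sum(w * bx^2)
    (num - w * bx * by) / (den - w * bx^2)
  }
  rss_of <- function(bx, by) {
    b_loo <- loo_slopes(bx, by, w)
    resid2 <- w * (by - b_loo * bx)^2
    list(rss = sum(resid2), resid2 = resid2)
  }
  obs <- rss_of(bx, by)
  b_loo_obs <- loo_slopes(bx, by, w)

  sims <- with_seed(seed, {
    sim_rss <- numeric(n_sim)
    sim_resid2 <- matrix(0, n_sim, k)
    for (i in seq_len(n_sim)) {
      bx_s <- stats::rnorm(k, bx, sx)
      by_s <- stats::rnorm(k, b_loo_obs * bx, sy)
      r <- rss_of(bx_s, by_s)
      sim_rss[i] <- r$rss
      sim_resid2[i, ] <- r$resid2
    }
    list(rss = sim_rss, resid2 = sim_resid2)
  })
  global_p <- (1 + sum(sims$rss >= obs$rss)) / (1 + n_sim)

  # plain empirical tail (no pseudocount): a gross outlier must be able to
  # reach p < alpha/k even at moderate n_sim
  outlier_p <- vapply(seq_len(k), function(j) {
    mean(sims$resid2[, j] >= obs$resid2[j])
  }, numeric(1))
  outliers <- integer(0)
  if (global_p < outlier_alpha) {
    outliers <- which(outlier_p * k < outlier_alpha)
  }

  raw <- ivw(mri, direction)
  raw$method <- "mr_presso_raw"
  if (length(outliers) > 0 && length(outliers) < k - 1) {
    adj <- ivw(mr_input(as.data.frame(mri)[-outliers, , drop = FALSE]),
               direction)
  } else {
    adj <- ivw(mri, direction)
  }
  adj$method <- "mr_presso_outlier_adjusted"
  adj$outliers_removed <- length(outliers)

  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < k - 1) {
    obs_dist <- (raw$b - adj$b) / abs(adj$b)
    sim_dist <- with_seed(child_seed(seed, 2L), {
      vapply(seq_len(n_sim), function(i) {
        drop_i <- sample(setdiff(seq_len(k), outliers), length(outliers))
        b_sub <- ivw_slope(bx[-drop_i], by[-drop_i], w[-drop_i])
        (raw$b - b_sub) / abs(b_sub)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(sim_dist) >= abs(obs_dist))) / (1 + n_sim)
  }

  list(raw = raw, outlier_adjusted = adj,
       outliers = mri$snp_id[outliers],
       global_rss = obs$rss, global_p = global_p,
       outlier_p = stats::setNames(outlier_p, mri$snp_id),
       distortion_p = distortion_p)
}

#' Multivariable MR
#'
#' Weighted least squares of the outcome betas on the matrix of exposure
#' betas without an intercept, weights 1/se_outcome^2, over the clumped
#' union of SNPs genome-wide significant for at least one exposure. Each
#' coefficient is the causal effect of that exposure conditional on the
#' others.
#'
#' @param beta_exposures Numeric matrix (k x p), one column per exposure
#'   (harmonized to the outcome).
#' @param beta_outcome,se_outcome Outcome effects and standard errors.
#' @param direction Direction label.
#' @return MR result data frame, one row per exposure.
#' @export
mvmr <- function(beta_exposures, beta_outcome, se_outcome,
                 direction = "exposure->outcome") {
  X <- as.matrix(beta_exposures)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(X)
  if (k <= ncol(X)) stop_param("mvmr needs more SNPs than exposures")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("exposure-beta matrix rank-deficient; collinear: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  w <- 1 / se_outcome^2
  fit <- stats::lm(beta_outcome ~ 0 + X, weights = w)
  sm <- summary(fit)
  cf <- sm$coefficients
  scale <- max(1, sm$sigma) / sm$sigma
  out <- lapply(seq_len(ncol(X)), function(j) {
    b <- cf[j, 1]
    se <- cf[j, 2] * scale
    r <- mr_result("mvmr", b, se,
                   2 * stats::pt(-abs(b / se), k - ncol(X)), k,
                   direction = direction)
    r$exposure <- colnames(X)[j]
    r
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR within direction-by-method groups
#'
#' Adjusted p-values are computed independently within each combination of
#' direction label and MR method, so each directional analysis and each
#' estimator carries its own false-discovery control.
#'
#' @param results MR result data frame with columns `method`, `direction`,
#'   `p`.
#' @return `results` with `p_adjusted` filled in.
#' @export
fdr_within_groups <- function(results) {
  stopifnot(all(c("method", "direction", "p") %in% names(results)))
  grp <- paste(results$direction, results$method, sep = "|")
  for (g in unique(grp)) {
    i <- which(grp == g)
    results$p_adjusted[i] <- stats::p.adjust(results$p[i], method = "BH")
  }
  results
}
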