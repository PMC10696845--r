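# End-to-end orchestration: meta-analysis -> PRS -> PheWAS (three cohorts,
# three trait sets) -> two-sample MR, on synthetic or user data, with a
# manifest recording seeds and counts at every filter.

#' Per-SNP association scan of a quantitative or binary trait
#'
#' Simple single-SNP regression of the phenotype on each dosage column
#' (closed-form least squares; missing dosages excluded per SNP), returning
#' GWAS-style summary statistics. Used by the pipeline to build cohort-level
#' summary statistics from individual-level synthetic data.
#'
#' @param G A `genotype_matrix`.
#' @param y Phenotype vector (0/1 for binary traits).
#' @param trait,cohort Labels for the result.
#' @return A `sumstats` object.
#' @export
gwas_scan <- function(G, y, trait = "trait", cohort = "cohort") {
  stopifnot(inherits(G, "genotype_matrix"), length(y) == nrow(G$dosages))
  m <- ncol(G$dosages)
  beta <- se <- numeric(m)
  n_used <- integer(m)
  for (j in seq_len(m)) {
    x <- G$dosages[, j]
    ok <- !is.na(x) & !is.na(y)
    xj <- x[ok]; yj <- y[ok]
    n <- length(xj)
    sxx <- sum((xj - mean(xj))^2)
    if (n < 3 || sxx == 0) {
      beta[j] <- 0; se[j] <- Inf; n_used[j] <- n
      next
    }
    b <- sum((xj - mean(xj)) * (yj - mean(yj))) / sxx
    rss <- sum((yj - mean(yj) - b * (xj - mean(xj)))^2)
    beta[j] <- b
    se[j] <- sqrt(rss / (n - 2) / sxx)
    n_used[j] <- n
  }
  ok <- is.finite(se) & se > 0
  v <- G$variants[ok, , drop = FALSE]
  sumstats(data.frame(
    snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$counted_allele, other_allele = v$other_allele,
    eaf = v$freq, beta = beta[ok], se = se[ok],
    p = pmin(1, pmax(.Machine$double.xmin,
                     2 * stats::pnorm(-abs(beta[ok] / se[ok])))),
    n = n_used[ok], stringsAsFactors = FALSE),
    trait = trait, cohort = cohort)
}

#' Build a pipeline run configuration
#'
#' Bundles the synthetic-cohort and MR generator configurations with the
#' analysis thresholds (all analysis defaults pre-filled) and the seeds of
#' every stochastic stage. The configuration round-trips through JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param cohort A [synth_cohort_config()] for the female cohort.
#' @param mr_cfg A [synth_mr_config()] for the MR stage.
#' @param thresholds Named list of analysis thresholds; defaults:
#'   genome-wide significance 5e-8, phecode minimum count 100, alpha 0.05,
#'   10 PCs, F > 10, statin Bonferroni divisor = number of biomarkers.
#' @param out_dir Output directory for result tables and the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = synth_cohort_config(
                         n_individuals = 4000L, n_snps = 300L,
                         n_causal = 60L, prevalence = 0.08,
                         h2_liability = 0.4, seed = seed),
                       mr_cfg = synth_mr_config(seed = child_seed(seed, 9L)),
                       thresholds = list(),
                       out_dir = tempfile("prsphewas_run_")) {
  defaults <- list(gw_p = 5e-8, phecode_min_count = 100, alpha = 0.05,
                   n_pcs = 10, f_min = 10, maf_min = 0.05, miss_max = 0.05,
                   hwe_p_min = 1e-6, n_statin_traits = 34)
  for (nm in names(thresholds)) defaults[[nm]] <- thresholds[[nm]]
  structure(list(seed = as.integer(seed), cohort = cohort, mr_cfg = mr_cfg,
                 thresholds = defaults, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$cohort <- unclass(x$cohort)
  x$mr_cfg <- unclass(x$mr_cfg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- x$cohort
  mc <- x$mr_cfg
  run_config(seed = x$seed,
             cohort = do.call(synth_cohort_config, cc),
             mr_cfg = do.call(synth_mr_config, mc),
             thresholds = x$thresholds,
             out_dir = x$out_dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# One cohort's PheWAS over the three trait sets. Returns result tables and
# filter counts for the manifest.
run_phewas_cohort <- function(G, prs, ids, records, map, thr, seed,
                              female = TRUE) {
  pcs <- pca_covariates(variant_qc(G, thr$maf_min, thr$miss_max,
                                   thr$hwe_p_min), k = thr$n_pcs)
  prs_z <- zscore(prs)
  age <- with_seed(child_seed(seed, 21L),
                   round(stats::runif(length(ids), 40, 69)))
  covs <- data.frame(pcs, age = age)

  phe_tab <- build_phecode_table(records, map, ids,
                                 min_count = thr$phecode_min_count)
  res_phe <- phewas_logistic(prs_z, phe_tab, covs)
  res_phe$bonferroni <- bonferroni_threshold(thr$alpha, max(1, nrow(res_phe)))
  res_phe$significant <- !is.na(res_phe$p) & res_phe$p < res_phe$bonferroni

  out <- list(phecodes = res_phe,
              counts = list(n_individuals = length(ids),
                            n_phecodes_tested = nrow(res_phe)))
  out
}

#' Run the full synthetic pipeline
#'
#' Executes the whole workflow on synthetic data: two half-cohort GWAS
#' scans of the simulated disease meta-analysed with per-cohort genomic
#' control; PRS scoring of the female, male and sensitivity cohorts with
#' the meta-analysis weights; phecode, biomarker and female-factor PheWAS
#' in each applicable cohort; and a two-sample MR stage (instrument
#' filters, IVW, MR-Egger, weighted median, leave-one-out, MR-PRESSO, FDR)
#' in both directions. All result tables are written as TSV under
#' `cfg$out_dir` together with a JSON manifest of seeds, thresholds and
#' filter counts. Identical seeds give byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- cfg$thresholds
  manifest <- list(package_version = as.character(
    utils::packageVersion("prsphewas")),
    seed = cfg$seed, thresholds = thr, stages = list())

  map <- read_phecode_map(
    system.file("extdata", "synthetic_icd10_phecode_map.csv",
                package = "prsphewas"),
    system.file("extdata", "synthetic_phecode_definitions.csv",
                package = "prsphewas"))

  ## females: genotypes, disease, meta-analysed GWAS weights, PRS
  G_f <- gen_genotypes(cfg$cohort)
  dis <- gen_disease(G_f, cfg$cohort)
  half <- seq_len(floor(nrow(G_f$dosages) / 2))
  sub_geno <- function(G, rows) genotype_matrix(
    G$dosages[rows, , drop = FALSE], G$variants, G$ids[rows])
  ss_a <- gwas_scan(sub_geno(G_f, half), dis$status[half],
                    "disease", "cohortA")
  ss_b <- gwas_scan(sub_geno(G_f, -half), dis$status[-half],
                    "disease", "cohortB")
  meta <- meta_fixed(list(ss_a, ss_b), apply_gc = TRUE)
  write_sumstats(meta, file.path(cfg$out_dir, "meta_sumstats.tsv"))
  manifest$stages$meta <- list(
    n_snps = nrow(meta$snps),
    lambdas = attr(meta, "report")$lambdas,
    dropped = length(attr(meta, "report")$dropped_snps))

  weights <- data.frame(snp_id = meta$snps$snp_id,
                        effect_allele = meta$snps$effect_allele,
                        weight = meta$snps$beta, stringsAsFactors = FALSE)
  prs_f <- prs_score(G_f, weights)

  ## males: independent genotypes, no disease
  male_cfg <- cfg$cohort
  male_cfg$seed <- child_seed(cfg$seed, 31L)
  male_cfg$n_individuals <- as.integer(ceiling(cfg$cohort$n_individuals * 0.8))
  G_m <- gen_genotypes(male_cfg)
  G_m$ids <- sub("^id", "m", G_m$ids)
  rownames(G_m$dosages) <- G_m$ids
  prs_m <- prs_score(G_m, weights)

  ## phecode-coded comorbidities: endometriosis phecode from true status,
  ## one PRS-linked comorbidity, one null comorbidity, adenomyosis-only flags
  mk_status <- function(ids, status, gval, seed) {
    with_seed(seed, {
      n <- length(ids)
      lin <- 0.3 * gval
      data.frame(id = ids,
                 `615` = as.logical(status),
                 `625` = stats::runif(n) <
                   stats::plogis(stats::qlogis(0.10) + lin),
                 `401` = stats::runif(n) < 0.15,
                 adenomyosis_only = !status & stats::runif(n) < 0.02,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
  }
  st_f <- mk_status(G_f$ids, dis$status, dis$genetic_value,
                    child_seed(cfg$seed, 41L))
  rec_f <- gen_icd10_records(st_f, map, misdiagnosis_rate = 0.05,
                             seed = child_seed(cfg$seed, 42L))
  st_m <- mk_status(G_m$ids, rep(0L, length(G_m$ids)),
                    rep(0, length(G_m$ids)), child_seed(cfg$seed, 43L))
  st_m$`615` <- NULL
  st_m$adenomyosis_only <- NULL
  rec_m <- gen_icd10_records(st_m, map, misdiagnosis_rate = 0.05,
                             seed = child_seed(cfg$seed, 44L))

  cases <- define_endometriosis_cases(rec_f, G_f$ids)
  sens_ids <- cases$sensitivity_ids
  manifest$stages$cases <- list(n_cases = sum(cases$case),
                                n_sensitivity = length(sens_ids))

  cohorts <- list(
    female = list(G = G_f, prs = prs_f, ids = G_f$ids, records = rec_f,
                  female = TRUE),
    male = list(G = G_m, prs = prs_m, ids = G_m$ids, records = rec_m,
                female = FALSE),
    sensitivity = local({
      rows <- match(sens_ids, G_f$ids)
      list(G = sub_geno(G_f, rows), prs = prs_f[rows], ids = sens_ids,
           records = rec_f[rec_f$id %in% sens_ids, , drop = FALSE],
           female = TRUE)
    })
  )

  phewas_results <- list()
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    res <- run_phewas_cohort(ch$G, ch$prs, ch$ids, ch$records, map, thr,
                             child_seed(cfg$seed, 50L + match(nm, names(cohorts))),
                             female = ch$female)
    ## biomarkers: one PRS-linked, one null, with the statin machinery
    gval <- if (nm == "male") rep(0, length(ch$ids)) else
      dis$genetic_value[match(ch$ids, G_f$ids)]
    seed_b <- child_seed(cfg$seed, 60L + match(nm, names(cohorts)))
    vis1 <- gen_biomarkers(ch$ids, gval, cfg$cohort, biomarker = "lipid",
                           prs_effect = 0.05, seed = seed_b,
                           sex = rep(if (ch$female) "F" else "M",
                                     length(ch$ids)))
    vis2 <- gen_biomarkers(ch$ids, gval, cfg$cohort, biomarker = "null_marker",
                           prs_effect = 0, seed = child_seed(seed_b, 2L),
                           sex = rep(if (ch$female) "F" else "M",
                                     length(ch$ids)))
    vis <- rbind(vis1, vis2)
    factors <- statin_correction_factors(vis)
    stat_cov <- vis1[c("deprivation", "age", "age_diff")]
    flags <- flag_statin_affected(vis, rbind(stat_cov, stat_cov),
                                  n_traits = thr$n_statin_traits)
    vis_adj <- adjust_biomarkers(vis, flags, factors)
    prs_z <- zscore(ch$prs)
    bcovs <- data.frame(fasting_time = vis1$fasting_time, age = vis1$age)
    vals <- list(
      lipid = vis_adj$value_enrol[vis_adj$biomarker == "lipid"],
      null_marker = vis_adj$value_enrol[vis_adj$biomarker == "null_marker"])
    res$biomarkers <- phewas_biomarkers(prs_z, vals, bcovs)
    nb <- max(1, nrow(res$biomarkers))
    res$biomarkers$bonferroni <- bonferroni_threshold(thr$alpha, nb)
    res$biomarkers$significant <- res$biomarkers$p < res$biomarkers$bonferroni
    res$statin <- list(factors = factors, flags = flags)

    if (ch$female) {
      ff <- gen_female_factors(ch$ids, gval,
                               shift = list(menarche = -0.1,
                                            cycle_length = -0.15),
                               out_of_range = 0.03,
                               seed = child_seed(cfg$seed,
                                                70L + match(nm, names(cohorts))))
      ffq <- female_factor_qc(ff)
      pcs <- pca_covariates(variant_qc(ch$G, thr$maf_min, thr$miss_max,
                                       thr$hwe_p_min), k = thr$n_pcs)
      res$female_factors <- phewas_female_factors(prs_z, ffq,
                                                  as.data.frame(pcs))
      nf <- max(1, nrow(res$female_factors))
      res$female_factors$bonferroni <- bonferroni_threshold(thr$alpha, nf)
      res$female_factors$significant <-
        res$female_factors$p < res$female_factors$bonferroni
    }
    phewas_results[[nm]] <- res
    write_tsv(res$phecodes,
              file.path(cfg$out_dir, sprintf("phewas_phecodes_%s.tsv", nm)))
    write_tsv(res$biomarkers,
              file.path(cfg$out_dir, sprintf("phewas_biomarkers_%s.tsv", nm)))
    if (!is.null(res$female_factors)) {
      write_tsv(res$female_factors,
                file.path(cfg$out_dir, sprintf("phewas_female_%s.tsv", nm)))
    }
    manifest$stages[[paste0("phewas_", nm)]] <- res$counts
  }

  summ <- significance_summary(lapply(phewas_results, `[[`, "phecodes"))
  write_tsv(summ, file.path(cfg$out_dir, "significance_summary.tsv"))

  ## MR stage, both directions
  sim <- gen_two_sample_sumstats(cfg$mr_cfg)
  mr_run <- function(exposure, outcome, direction, seed) {
    mri <- harmonize(exposure, outcome)
    n0 <- nrow(mri)
    mri <- f_statistics(mri, thr$f_min)
    n1 <- nrow(mri)
    mri <- steiger_filter(mri)
    n2 <- nrow(mri)
    res <- rbind(ivw(mri, direction),
                 mr_egger(mri, direction),
                 weighted_median(mri, seed = seed, direction = direction))
    pr <- mr_presso(mri, seed = child_seed(seed, 2L), direction = direction)
    res <- rbind(res, pr$raw, pr$outlier_adjusted)
    loo <- leave_one_out(mri)
    list(results = res, loo = loo, presso = pr,
         counts = list(k_harmonized = n0, k_after_f = n1,
                       k_after_steiger = n2))
  }
  # a direction can legitimately run out of instruments (e.g. the Steiger
  # filter removes everything in the non-causal direction); record, not fail
  try_mr <- function(...) tryCatch(mr_run(...), error = function(e) {
    list(results = NULL, loo = NULL, presso = NULL,
         counts = list(error = conditionMessage(e)))
  })
  fwd <- try_mr(sim$exposure, sim$outcome, "exposure->outcome",
                child_seed(cfg$seed, 81L))
  rev <- try_mr(sim$outcome, sim$exposure, "outcome->exposure",
                child_seed(cfg$seed, 82L))
  mr_tab <- fdr_within_groups(rbind(fwd$results, rev$results))
  write_tsv(mr_tab, file.path(cfg$out_dir, "mr_results.tsv"))
  if (!is.null(fwd$loo)) {
    write_tsv(fwd$loo, file.path(cfg$out_dir, "mr_leave_one_out.tsv"))
  }
  manifest$stages$mr <- list(forward = fwd$counts, reverse = rev$counts,
                             presso_outliers = length(fwd$presso$outliers))

  ## filter-count arithmetic must be self-consistent
  if (is.null(fwd$counts$error)) {
    stopifnot(fwd$counts$k_harmonized >= fwd$counts$k_after_f,
              fwd$counts$k_after_f >= fwd$counts$k_after_steiger)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Cross-cohort replication summary
#'
#' For every trait significant in at least one cohort at its Bonferroni
#' threshold, reports the per-cohort significance flags and a replication
#' label relative to the first cohort: "bonferroni replication" when
#' significant in another cohort at the corrected threshold, "nominal
#' replication" at p < 0.05, otherwise "no replication".
#'
#' @param results_by_cohort Named list of PheWAS result data frames (with
#'   columns `trait`, `p`, `bonferroni`, `significant`).
#' @return Data frame, one row per trait significant anywhere.
#' @export
significance_summary <- function(results_by_cohort) {
  stopifnot(length(results_by_cohort) >= 1)
  nms <- names(results_by_cohort)
  traits <- unique(unlist(lapply(results_by_cohort, function(df) {
    df$trait[!is.na(df$significant) & df$significant]
  })))
  if (length(traits) == 0) {
    return(data.frame(trait = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(traits, function(tr) {
    row <- list(trait = tr)
    for (nm in nms) {
      df <- results_by_cohort[[nm]]
      i <- match(tr, df$trait)
      p <- if (is.na(i)) NA_real_ else df$p[i]
      sig <- if (is.na(i)) NA else isTRUE(df$significant[i])
      row[[paste0("p_", nm)]] <- p
      row[[paste0("sig_", nm)]] <- sig
      row[[paste0("replication_", nm)]] <-
        if (is.na(i) || is.na(p)) "not tested"
        else if (sig) "bonferroni replication"
        else if (p < 0.05) "nominal replication"
        else "no replication"
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
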