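#!/usr/bin/env Rscript
# Stage 1: fix the study configuration and generate the synthetic inputs.
#
# Everything downstream regenerates deterministically from the
# configuration written here, so only the config and the (small)
# two-sample GWAS summary statistics are materialised.

suppressPackageStartupMessages(library(prsphewas))

seed <- 20260924L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- run_config(
  seed = seed,
  cohort = synth_cohort_config(n_individuals = 4000L, n_snps = 300L,
                               n_causal = 60L, prevalence = 0.08,
                               h2_liability = 0.4, seed = seed),
  mr_cfg = synth_mr_config(true_b = -0.2, k_instruments = 30L,
                           n_exposure = 200000L, n_outcome = 100000L,
                           seed = seed + 9L),
  thresholds = list(phecode_min_count = 50),
  out_dir = "results/pipeline")
write_run_config(cfg, "results/run_config.json")

G <- gen_genotypes(cfg$cohort)
d <- gen_disease(G, cfg$cohort)
cat(sprintf("cohort: %d individuals x %d SNPs, %.2f%% dosages missing\n",
            nrow(G$dosages), ncol(G$dosages),
            100 * mean(is.na(G$dosages))))
cat(sprintf("disease: prevalence %.3f (configured %.3f), h2 %.2f, %d causal SNPs\n",
            mean(d$status), cfg$cohort$prevalence,
            cfg$cohort$h2_liability, nrow(d$effects)))

sim <- gen_two_sample_sumstats(cfg$mr_cfg)
write_sumstats(sim$exposure, "results/data/exposure_sumstats.tsv")
write_sumstats(sim$outcome, "results/data/outcome_sumstats.tsv")
cat(sprintf("two-sample GWAS pair: %d instruments, true causal effect %.2f\n",
            cfg$mr_cfg$k_instruments, cfg$mr_cfg$true_b))
cat("wrote results/run_config.json and results/data/*.tsv\n")
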