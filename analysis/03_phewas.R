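#!/usr/bin/env Rscript
# Stage 3: run the orchestrated pipeline (meta -> PRS -> PheWAS x three
# cohorts x three trait sets -> MR) and narrate the PheWAS findings.

suppressPackageStartupMessages(library(prsphewas))

cfg <- read_run_config("results/run_config.json")
manifest <- run_all(cfg)
cat(sprintf("pipeline complete; outputs under %s\n", cfg$out_dir))
cat(sprintf("endometriosis-style cases: %d; sensitivity cohort: %d\n",
            manifest$stages$cases$n_cases,
            manifest$stages$cases$n_sensitivity))

for (nm in c("female", "male", "sensitivity")) {
  phe <- utils::read.delim(file.path(cfg$out_dir,
                                     sprintf("phewas_phecodes_%s.tsv", nm)))
  sig <- phe[!is.na(phe$significant) & phe$significant, ]
  cat(sprintf("%s cohort: %d phecodes tested, %d significant (%s)\n",
              nm, nrow(phe), nrow(sig),
              if (nrow(sig)) paste(sig$trait, collapse = ", ") else "-"))
}

summ <- utils::read.delim(file.path(cfg$out_dir,
                                    "significance_summary.tsv"))
if (nrow(summ) > 0) {
  cat("cross-cohort replication of significant phecodes:\n")
  print(summ[, grep("^(trait|replication_)", names(summ))],
        row.names = FALSE)
}

bio <- utils::read.delim(file.path(cfg$out_dir,
                                   "phewas_biomarkers_female.tsv"))
cat("female biomarker PheWAS (log-scale estimate per PRS SD):\n")
print(bio[c("trait", "estimate", "se", "p", "significant")],
      row.names = FALSE)

ff <- utils::read.delim(file.path(cfg$out_dir, "phewas_female_female.tsv"))
cat("female-specific factor PheWAS:\n")
print(ff[c("trait", "model", "estimate", "se", "p", "significant")],
      row.names = FALSE)
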