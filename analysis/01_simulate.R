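#!/usr/bin/env Rscript
# Stage 1: simulate the three-cohort study (two discovery cohorts plus an
# external validation cohort on a noisier platform) and write each cohort's
# expression matrix and sample table under results/cohorts/.

suppressPackageStartupMessages(library(radresp))

out_dir <- "results/cohorts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(
  n_genes = 1200,
  cohort_sizes = c(grampian = 125, aristotle = 124, validation = 107),
  pcr_prevalence = c(grampian = 0.26, aristotle = 0.19, validation = 0.21),
  n_signal_up = 40, n_signal_down = 40, effect_size_sd_units = 1.5,
  validation_cohort = "validation", seed = 20240101)
study <- simulate_study(cfg)

for (nm in names(study$cohorts)) {
  co <- study$cohorts[[nm]]
  write_expression(co$expr, file.path(out_dir, paste0(nm, "_expr.tsv")))
  write_sample_table(co$samples, file.path(out_dir, paste0(nm, "_samples.tsv")))
}
jsonlite::write_json(
  list(up_genes = study$truth$up_genes, down_genes = study$truth$down_genes),
  "results/truth.json", auto_unbox = FALSE)

merged <- merge_cohorts(lapply(study$cohorts[c("grampian", "aristotle")],
                               `[[`, "samples"))
cat(sprintf("discovery: %d samples, %d pCR (%.1f%%)\n",
            merged$n, merged$n_pcr, 100 * merged$prevalence))
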