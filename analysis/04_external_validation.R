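#!/usr/bin/env Rscript
# Stage 4: external validation of the locked model on the held-out cohort,
# under both batch-correction modes, defended by a size-matched random
# gene-set permutation null.

suppressPackageStartupMessages(library(radresp))

model <- load_model("results/locked_model.json")
val_samples <- read_sample_table("results/cohorts/validation_samples.tsv")
all_samples <- do.call(rbind, lapply(
  c("grampian", "aristotle", "validation"),
  function(nm) read_sample_table(sprintf("results/cohorts/%s_samples.tsv", nm))))
disc_ids <- setdiff(all_samples$sample_id, val_samples$sample_id)

rows <- lapply(c("supervised", "agnostic"), function(mode) {
  corrected <- read_expression(sprintf("results/corrected_%s.tsv", mode))
  rep <- validate_model(model, corrected[, val_samples$sample_id], val_samples)
  data.frame(mode = mode, auc = rep$auc,
             auc_lo = rep$auc_ci[1], auc_hi = rep$auc_ci[2],
             sensitivity = rep$sensitivity, specificity = rep$specificity,
             accuracy = rep$accuracy,
             TP = rep$TP, FP = rep$FP, TN = rep$TN, FN = rep$FN)
})
val <- do.call(rbind, rows)
write.table(val, "results/validation_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(val[, c("mode", "auc", "sensitivity", "specificity")])

corrected <- read_expression("results/corrected_supervised.tsv")
obs_auc <- val$auc[val$mode == "supervised"]
pn <- permutation_null(corrected, all_samples, disc_ids,
                       val_samples$sample_id, observed_auc = obs_auc,
                       m = length(model$gene_list), B = 200, seed = 104,
                       mode = "score_only")
write.table(data.frame(observed_auc = obs_auc,
                       null_mean_auc = mean(pn$null_auc),
                       null_sd_auc = sd(pn$null_auc),
                       B = length(pn$null_auc), p = pn$p,
                       p_strict = pn$p_strict),
            "results/permutation_null.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("permutation null: observed %.3f vs null mean %.3f, p = %.4g\n",
            obs_auc, mean(pn$null_auc), pn$p))
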