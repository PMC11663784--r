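#!/usr/bin/env Rscript
# Stage 3: hypothesis-free ML discovery. QC the pooled discovery cohorts,
# select robust DEGs over repeated class-balanced subsets, shrink them to a
# minimal panel, batch-correct (supervised mode) across all three cohorts,
# run the cross-validated algorithm/gene-set competition, and lock the
# winning model.

suppressPackageStartupMessages(library(radresp))

read_cohort <- function(nm) {
  list(expr = read_expression(sprintf("results/cohorts/%s_expr.tsv", nm)),
       samples = read_sample_table(sprintf("results/cohorts/%s_samples.tsv", nm)))
}
cohorts <- lapply(c("grampian", "aristotle", "validation"), read_cohort)
names(cohorts) <- c("grampian", "aristotle", "validation")

disc_expr <- cbind(cohorts$grampian$expr, cohorts$aristotle$expr)
disc_samples <- rbind(cohorts$grampian$samples, cohorts$aristotle$samples)

qc <- quality_check(disc_expr, disc_samples)
cat(sprintf("QC: dropped %d genes, %d samples\n",
            length(qc$report$dropped_genes), length(qc$report$dropped_samples)))
disc_expr <- qc$expr
disc_samples <- disc_samples[disc_samples$sample_id %in% colnames(disc_expr), ]

subsets <- balance_iterations(disc_samples, n_iter = 20, seed = 101)
degs <- select_degs(disc_expr, disc_samples, subsets)
write.table(degs, "results/deg_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
robust <- degs$gene[degs$robust]
cat(sprintf("robust DEGs: %d of %d genes\n", length(robust), nrow(degs)))

dmgs <- select_dmgs(disc_expr, disc_samples, robust, seed = 102)
write.table(attr(dmgs, "trace"), "results/dmg_trace.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# supervised batch correction fitted across all cohorts; the corrected
# matrices are reused by stages 4 and 5
all_expr <- do.call(cbind, lapply(cohorts, function(co) co$expr[rownames(disc_expr), ]))
all_samples <- do.call(rbind, lapply(cohorts, `[[`, "samples"))
for (mode in c("supervised", "agnostic")) {
  cm <- fit_combat(all_expr, all_samples, mode = mode)
  write_expression(cm$corrected,
                   sprintf("results/corrected_%s.tsv", mode))
}
corrected <- read_expression("results/corrected_supervised.tsv")

trained <- train_and_select(corrected[, disc_samples$sample_id], disc_samples,
                            deg_genes = robust, dmg_genes = dmgs,
                            seed = 103,
                            algorithms = c("l1_logistic", "elastic_net",
                                           "boosted_trees", "random_forest"),
                            k = 10)
write.table(trained$cv_table, "results/cv_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
save_model(trained$model, "results/locked_model.json")
cat(sprintf("locked model: %s on %d genes (CV accuracy %.3f)\n",
            trained$model$algorithm_id, length(trained$model$gene_list),
            trained$model$cv_accuracy))
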