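#!/usr/bin/env Rscript
# Stage 5: biological characterisation. Rank genes by the pCR contrast on
# the corrected discovery data, test gene sets by preranked GSEA, pool
# gene-score associations across the discovery cohorts by fixed-effect
# meta-analysis, and assign cell-type specificity from a reference matrix.

suppressPackageStartupMessages(library(radresp))

corrected <- read_expression("results/corrected_supervised.tsv")
read_cohort <- function(nm) {
  list(expr = read_expression(sprintf("results/cohorts/%s_expr.tsv", nm)),
       samples = read_sample_table(sprintf("results/cohorts/%s_samples.tsv", nm)))
}
disc <- lapply(c("grampian", "aristotle"), read_cohort)
names(disc) <- c("grampian", "aristotle")
disc_samples <- do.call(rbind, lapply(disc, `[[`, "samples"))
truth <- jsonlite::fromJSON("results/truth.json")

## preranked GSEA on the pCR contrast
ranking <- rank_genes(corrected[, disc_samples$sample_id], disc_samples$pcr)
metric <- setNames(ranking$metric, ranking$gene)
set.seed(105)
sets <- list(planted_up = truth$up_genes,
             planted_down = truth$down_genes,
             random_a = sample(ranking$gene, 40),
             random_b = sample(ranking$gene, 40))
enr <- gsea_preranked(metric, sets, n_perm = 2000, seed = 106)
enr$leading_edge <- vapply(enr$leading_edge, paste, "", collapse = ",")
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(enr[, c("set", "es", "nes", "p_value", "fdr")])

## per-cohort gene ~ compound-score associations pooled by meta-analysis
scores <- read.delim("results/candidate_scores.tsv")
score_list <- lapply(disc, function(co) {
  idx <- match(co$samples$sample_id, scores$sample_id)
  list(compound = setNames(scores$compound[idx], co$samples$sample_id))
})
expr_list <- lapply(disc, `[[`, "expr")
top_genes <- ranking$gene[c(1:10, (nrow(ranking) - 9):nrow(ranking))]
meta <- gene_feature_meta(expr_list, score_list, genes = top_genes)
write.table(meta, "results/gene_score_meta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## cell-type specificity of the top-ranked genes against a synthetic
## mean-expression reference (strongest-vs-second fold-change rule)
set.seed(107)
celltypes <- c("epithelial", "leucocyte", "endothelial", "fibroblast")
reference <- matrix(rexp(length(top_genes) * 4, rate = 0.5),
                    nrow = length(top_genes),
                    dimnames = list(top_genes, celltypes))
reference[1:5, "epithelial"] <- reference[1:5, "epithelial"] + 10
assigned <- assign_cell_types(reference, top_genes)
write.table(assigned, "results/cell_types.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("cell-type specific genes: %d of %d\n",
            sum(assigned$assigned != "none"), nrow(assigned)))
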