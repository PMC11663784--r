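brute_es <- function(metric, set, p = 1) {
  N <- length(metric)
  hits <- names(metric) %in% set
  w <- abs(metric)^p
  nr <- sum(w[hits])
  run <- cumsum(ifelse(hits, w / nr, -1 / (N - sum(hits))))
  run[which.max(abs(run))]
}

test_that("rank_genes orders by signed SMD with gene-id tie-break", {
  samp <- make_samples(30, 15)
  x <- make_expr(20, samp, shift_genes = c("g0003", "g0007"), shift = 2,
                 seed = 121)
  r <- rank_genes(x, samp$pcr)
  expect_setequal(r$gene[1:2], c("g0003", "g0007"))
  expect_true(all(diff(r$metric) <= 0))
  # oracle for a single gene
  g <- "g0010"
  y <- samp$pcr
  v <- x[g, ]
  sp <- sqrt(((sum(y == 1) - 1) * var(v[y == 1]) +
              (sum(y == 0) - 1) * var(v[y == 0])) / (length(y) - 2))
  expect_equal(r$metric[r$gene == g],
               (mean(v[y == 1]) - mean(v[y == 0])) / sp, tolerance = 1e-12)
  expect_error(rank_genes(x, rep(1, 30)), class = "radresp_validation_error")
})

test_that("GSEA enrichment score equals the brute-force running sum", {
  set.seed(122)
  for (i in 1:5) {
    metric <- sort(rnorm(20), decreasing = TRUE)
    names(metric) <- paste0("g", 1:20)
    set <- sample(names(metric), 6)
    got <- gsea_preranked(metric, list(s = set), n_perm = 50, seed = 1,
                          min_size = 3)
    expect_equal(got$es, brute_es(metric, set), tolerance = 1e-12)
  }
})

test_that("unweighted ES of a set and its complement are opposite", {
  set.seed(123)
  metric <- sort(rnorm(16), decreasing = TRUE)
  names(metric) <- paste0("g", 1:16)
  s <- sample(names(metric), 7)
  a <- gsea_preranked(metric, list(x = s), weight_p = 0, n_perm = 10,
                      seed = 1, min_size = 3)
  b <- gsea_preranked(metric, list(x = setdiff(names(metric), s)),
                      weight_p = 0, n_perm = 10, seed = 1, min_size = 3)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("GSEA agrees with fgsea on the enrichment score", {
  set.seed(124)
  metric <- sort(rnorm(50), decreasing = TRUE)
  names(metric) <- paste0("g", 1:50)
  sets <- list(up = paste0("g", 1:8), spread = paste0("g", seq(2, 50, by = 7)))
  got <- gsea_preranked(metric, sets, n_perm = 100, seed = 2, min_size = 3)
  ref <- suppressWarnings(
    fgsea::fgsea(pathways = sets, stats = metric, minSize = 3, maxSize = 500,
                 nPermSimple = 200))
  expect_equal(got$es[match(ref$pathway, got$set)], ref$ES, tolerance = 1e-10)
})

test_that("GSEA finds a top-loaded set enriched and significant", {
  set.seed(125)
  metric <- sort(rnorm(200), decreasing = TRUE)
  names(metric) <- sprintf("g%03d", 1:200)
  sets <- list(top = names(metric)[1:15],
               random = sample(names(metric), 15))
  got <- gsea_preranked(metric, sets, n_perm = 500, seed = 3)
  top <- got[got$set == "top", ]
  expect_gt(top$es, 0)
  expect_identical(top$direction, "up_in_class1")
  expect_lt(top$p_value, 0.01)
  expect_gt(top$nes, 1)
  # leading edge is a prefix subset of the set within the ranking
  le <- top$leading_edge[[1]]
  expect_true(all(le %in% sets$top))
  expect_gt(length(le), 0)
  # small sets are skipped with a warning
  expect_warning(gsea_preranked(metric, list(tiny = names(metric)[1:2]),
                                n_perm = 10, seed = 1), "skipped")
})

test_that("GSEA is deterministic given a seed and BH-adjusts across sets", {
  set.seed(126)
  metric <- sort(rnorm(80), decreasing = TRUE)
  names(metric) <- sprintf("g%02d", 1:80)
  sets <- list(a = names(metric)[1:10], b = sample(names(metric), 10),
               c = sample(names(metric), 12))
  g1 <- gsea_preranked(metric, sets, n_perm = 200, seed = 7)
  g2 <- gsea_preranked(metric, sets, n_perm = 200, seed = 7)
  expect_identical(g1, g2)
  expect_equal(g1$fdr, p.adjust(g1$p_value, "BH"))
})

test_that("concordance_of_contrasts partitions sets and checks signs", {
  a <- data.frame(set = c("s1", "s2", "s3"), es = c(0.5, -0.4, 0.3),
                  fdr = c(0.01, 0.02, 0.5), stringsAsFactors = FALSE)
  b <- data.frame(set = c("s1", "s2", "s4"), es = c(0.6, 0.4, -0.2),
                  fdr = c(0.01, 0.01, 0.1), stringsAsFactors = FALSE)
  got <- concordance_of_contrasts(a, b, fdr_cut = 0.25)
  expect_setequal(got$shared$set, c("s1", "s2"))
  expect_identical(got$shared$same_direction[got$shared$set == "s1"], TRUE)
  expect_identical(got$shared$same_direction[got$shared$set == "s2"], FALSE)
  expect_identical(got$a_only, character(0))
  expect_identical(got$b_only, "s4")
  expect_equal(got$sign_agreement, 0.5)
})

test_that("gene_feature_meta pools per-cohort OLS slopes like metafor", {
  set.seed(127)
  make_cohort <- function(n, prefix) {
    sc <- rnorm(n)
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    e <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("gA", "gB"), ids))
    e["gA", ] <- e["gA", ] + 0.8 * sc
    list(expr = e, scores = list(f = setNames(sc, ids)))
  }
  c1 <- make_cohort(40, "a"); c2 <- make_cohort(50, "b")
  got <- gene_feature_meta(list(c1 = c1$expr, c2 = c2$expr),
                           list(c1 = c1$scores, c2 = c2$scores),
                           genes = c("gA", "gB"))
  # oracle: per-cohort lm slopes pooled by metafor FE
  betas <- ses <- numeric(2)
  for (i in 1:2) {
    co <- list(c1, c2)[[i]]
    f <- lm(co$expr["gA", ] ~ co$scores$f)
    betas[i] <- coef(summary(f))[2, 1]; ses[i] <- coef(summary(f))[2, 2]
  }
  fe <- metafor::rma(yi = betas, sei = ses, method = "FE")
  row <- got[got$gene == "gA" & got$feature == "f", ]
  expect_equal(row$beta, as.numeric(coef(fe)), tolerance = 1e-10)
  expect_equal(row$se, fe$se, tolerance = 1e-10)
  expect_equal(row$k, 2L)
  # gA truly associated, gB not
  expect_lt(row$p, 0.01)
  expect_gt(got$p[got$gene == "gB"], 0.01)
})

test_that("cell-type assignment uses top/second fold change, inclusive", {
  ref <- rbind(epi = c(epithelial = 8, leucocyte = 2, endothelial = 1,
                       fibroblast = 1),
               amb = c(epithelial = 4, leucocyte = 3, endothelial = 2,
                       fibroblast = 1),
               edge = c(epithelial = 4, leucocyte = 2, endothelial = 1,
                        fibroblast = 1))
  got <- assign_cell_types(ref, c("epi", "amb", "edge"))
  expect_identical(got$assigned[got$gene == "epi"], "epithelial")
  expect_identical(got$assigned[got$gene == "amb"], "none")  # 4/3 < 2
  expect_identical(got$assigned[got$gene == "edge"], "epithelial")  # 4/2 = 2
  expect_equal(got$fold_change[got$gene == "edge"], 2)
  expect_warning(got2 <- assign_cell_types(ref, "missing_gene"), "absent")
  expect_identical(got2$assigned, "none")
})
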