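test_that("quality_check drops bad genes, imputes, and flags noise samples", {
  samp <- make_samples(20, 10)
  x <- make_expr(40, samp, seed = 71)
  # real expression has per-gene baselines, which is what makes samples
  # correlate with the cohort median profile
  set.seed(70)
  x <- x + rnorm(40, 0, 3)
  # clean matrix: nothing removed
  qc0 <- quality_check(x, samp)
  expect_identical(qc0$expr, x)
  expect_length(qc0$report$dropped_genes, 0)
  expect_length(qc0$report$dropped_samples, 0)
  # gene with 10% missing at threshold 0.05 -> dropped
  x1 <- x; x1["g0001", 1:2] <- NA
  qc1 <- quality_check(x1, samp)
  expect_identical(qc1$report$dropped_genes, "g0001")
  # gene with tolerable missingness -> median-imputed
  x2 <- x; x2["g0002", 1] <- NA
  qc2 <- quality_check(x2, samp)
  expect_false("g0002" %in% qc2$report$dropped_genes)
  expect_equal(qc2$expr["g0002", 1], median(x2["g0002", ], na.rm = TRUE))
  # one sample replaced by independent noise -> removed (oracle: direct
  # correlation to the cohort median profile)
  x3 <- x
  set.seed(72)
  x3[, 5] <- rnorm(40, 7)
  ref <- apply(x3, 1, median)
  expect_lt(cor(x3[, 5], ref), 0.7)
  qc3 <- quality_check(x3, samp)
  expect_identical(qc3$report$dropped_samples, colnames(x)[5])
  expect_false(colnames(x)[5] %in% colnames(qc3$expr))
})

test_that("quality_check aborts when most samples fail", {
  samp <- make_samples(8, 4)
  set.seed(73)
  x <- matrix(rnorm(30 * 8, 7), 30, 8,
              dimnames = list(sprintf("g%04d", 1:30), samp$sample_id))
  expect_error(quality_check(x, samp, qc_corr_min = 0.99),
               class = "radresp_qc_error")
})

test_that("balance iterations: all minority kept, equal majority draw", {
  samp <- make_samples(50, 10)
  subs <- balance_iterations(samp, n_iter = 5, seed = 2)
  pos <- samp$sample_id[samp$pcr == 1]
  for (s in subs) {
    expect_length(s, 20)
    expect_true(all(pos %in% s))
    expect_false(anyDuplicated(s) > 0)
  }
  # determinism
  expect_identical(subs, balance_iterations(samp, n_iter = 5, seed = 2))
  expect_false(identical(subs, balance_iterations(samp, n_iter = 5, seed = 3)))
  # already balanced: every iteration is the full cohort
  bal <- make_samples(40, 20)
  subs2 <- balance_iterations(bal, n_iter = 3, seed = 1)
  for (s in subs2) expect_setequal(s, bal$sample_id)
})

test_that("majority-sample appearance frequency matches the binomial oracle", {
  samp <- make_samples(50, 10)
  subs <- balance_iterations(samp, n_iter = 200, seed = 7)
  neg <- samp$sample_id[samp$pcr == 0]
  freq <- vapply(neg, function(id) sum(vapply(subs, function(s) id %in% s,
                                              logical(1))), numeric(1))
  # each negative drawn with p = 10/40 per iteration; 99.9% band at B=200
  expect_true(all(freq >= qbinom(5e-4, 200, 0.25)))
  expect_true(all(freq <= qbinom(1 - 5e-4, 200, 0.25)))
  expect_lt(abs(mean(freq) - 50), 3)
})

test_that("balance iterations reject impossible designs", {
  samp <- make_samples(10, 9)  # minority = negatives (1)
  expect_error(balance_iterations(samp, 2, 1), class = "radresp_validation_error")
  one <- make_samples(10, 10)
  expect_error(balance_iterations(one, 2, 1), class = "radresp_validation_error")
})

test_that("moderated t matches the limma oracle", {
  set.seed(74)
  G <- 150; n1 <- 12; n0 <- 18
  y <- rep(c(1, 0), c(n1, n0))
  x <- matrix(rnorm(G * (n1 + n0)), G, n1 + n0) * exp(rnorm(G, 0, 0.5))
  dimnames(x) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:(n1 + n0)))
  got <- radresp:::moderated_t(x, y)
  fit <- limma::eBayes(limma::lmFit(x, model.matrix(~ factor(y, levels = c(0, 1)))))
  expect_equal(unname(got$statistic), unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(unname(got$p_value), unname(fit$p.value[, 2]), tolerance = 1e-10)
  expect_equal(got$df_prior, fit$df.prior, tolerance = 1e-6)
  expect_equal(got$s2_prior, fit$s2.prior, tolerance = 1e-8)
})

test_that("moderated t matches limma when variances are homogeneous", {
  # homogeneous variances push the prior df to infinity: different code path
  set.seed(75)
  G <- 120
  y <- rep(c(1, 0), c(10, 14))
  x <- matrix(rnorm(G * 24), G, 24)
  got <- radresp:::moderated_t(x, y)
  fit <- limma::eBayes(limma::lmFit(x, model.matrix(~ factor(y, levels = c(0, 1)))))
  expect_equal(unname(got$statistic), unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(unname(got$p_value), unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("rank-sum matches wilcox.test with ties and continuity correction", {
  set.seed(76)
  y <- rep(c(1, 0), c(9, 13))
  x <- rbind(matrix(rnorm(50 * 22), 50, 22),
             matrix(round(rnorm(30 * 22) * 2) / 2, 30, 22))  # ties
  got <- radresp:::rank_sum(x, y)
  oracle <- apply(x, 1, function(r) {
    wilcox.test(r[y == 1], r[y == 0], exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(unname(got$p_value), unname(oracle), tolerance = 1e-12)
})

test_that("select_degs: strong planted genes always selected, null never", {
  samp <- make_samples(80, 40)
  planted <- sprintf("g%04d", 1:4)
  x <- make_expr(300, samp, shift_genes = planted, shift = 3, seed = 77)
  x["g0005", ] <- x["g0005", 1]  # constant gene: statistic 0 / p 1 path
  subs <- balance_iterations(samp, n_iter = 10, seed = 5)
  res <- select_degs(x, samp, subs)
  expect_true(all(res$robust[res$gene %in% planted]))
  expect_equal(res$n_iterations_selected[res$gene == "g0005"], 0L)
  expect_false(res$robust[res$gene == "g0005"])
  # robust <=> selected in all N
  expect_identical(res$robust, res$n_iterations_selected == length(subs))
})

test_that("select_degs on a null matrix gives an (almost surely) empty set", {
  samp <- make_samples(60, 30)
  x <- make_expr(1000, samp, seed = 78)
  subs <- balance_iterations(samp, n_iter = 10, seed = 9)
  res <- select_degs(x, samp, subs)
  expect_equal(sum(res$robust), 0L)
})

test_that("select_dmgs finds a dominating gene and honours the floor", {
  samp <- make_samples(60, 30)
  x <- make_expr(40, samp, seed = 79)
  # one near-perfectly separating gene among noise
  x["g0001", ] <- 7 + 3 * samp$pcr + rnorm(60, sd = 0.1)
  got <- select_dmgs(x, samp, rownames(x), seed = 3)
  expect_true("g0001" %in% got)
  expect_lt(length(got), 40)
  tr <- attr(got, "trace")
  expect_true(is.data.frame(tr) && all(c("size", "accuracy") %in% names(tr)))
  # tol_acc = 1 returns the floor set regardless
  floor_set <- select_dmgs(x, samp, rownames(x), seed = 3, tol_acc = 1)
  expect_length(floor_set, 5)
  # determinism
  expect_identical(select_dmgs(x, samp, rownames(x), seed = 3),
                   select_dmgs(x, samp, rownames(x), seed = 3))
  expect_error(select_dmgs(x, samp, character(0)),
               class = "radresp_validation_error")
})

test_that("train_and_select: separable data, tie-break prefers fewer genes", {
  samp <- make_samples(40, 20)
  x <- make_expr(25, samp, seed = 81)
  x["g0001", ] <- 7 + 4 * samp$pcr + rnorm(40, sd = 0.05)
  got <- train_and_select(x, samp, deg_genes = rownames(x)[1:20],
                          dmg_genes = "g0001", seed = 5,
                          algorithms = c("l1_logistic", "boosted_trees"), k = 5)
  expect_s3_class(got$model, "locked_model")
  best <- max(got$cv_table$mean_accuracy, na.rm = TRUE)
  expect_gte(best, 0.95)
  # among configurations at the top accuracy, the winner has the fewest genes
  top <- got$cv_table[!got$cv_table$failed &
                      got$cv_table$mean_accuracy == best, ]
  expect_equal(length(got$model$gene_list), min(top$n_genes))
  expect_identical(got$model$gene_list, "g0001")
})

test_that("train_and_select under permuted labels stays near chance", {
  set.seed(82)
  samp <- make_samples(60, 30)
  x <- make_expr(30, samp, seed = 83)
  samp$pcr <- sample(samp$pcr)  # destroy any accidental structure
  got <- train_and_select(x, samp, deg_genes = rownames(x)[1:10],
                          dmg_genes = rownames(x)[1:5], seed = 7,
                          algorithms = "l1_logistic", k = 5)
  accs <- got$cv_table$mean_accuracy
  # binomial 95% band of 0.5 at n=60, widened for CV fold noise
  expect_true(all(abs(accs - 0.5) < 0.20))
})

test_that("train_and_select is deterministic and leak-free", {
  samp <- make_samples(36, 18)
  x <- make_expr(20, samp, shift_genes = c("g0001", "g0002"), shift = 2,
                 seed = 85)
  a <- train_and_select(x, samp, rownames(x)[1:10], rownames(x)[1:4],
                        seed = 11, algorithms = "boosted_trees", k = 4)
  b <- train_and_select(x, samp, rownames(x)[1:10], rownames(x)[1:4],
                        seed = 11, algorithms = "boosted_trees", k = 4)
  expect_identical(model_hash(a$model), model_hash(b$model))
  # perturbing data outside the discovery samples cannot change the model:
  # train on the same discovery matrix explicitly restricted
  x2 <- cbind(x, extra = rnorm(20, 7))
  colnames(x2)[ncol(x2)] <- "ghost_sample"
  c <- train_and_select(x2[, samp$sample_id], samp, rownames(x)[1:10],
                        rownames(x)[1:4], seed = 11,
                        algorithms = "boosted_trees", k = 4)
  expect_identical(model_hash(a$model), model_hash(c$model))
})

test_that("every registry algorithm fits and predicts probabilities", {
  samp <- make_samples(30, 15)
  x <- make_expr(12, samp, shift_genes = c("g0001", "g0002"), shift = 2,
                 seed = 87)
  y <- as.numeric(samp$pcr)
  xt <- t(x)
  for (alg in names(radresp:::learner_registry())) {
    hyper <- radresp:::learner_registry()[[alg]]$grid[[1]]
    payload <- radresp:::learner_fit(alg, xt, y, hyper, seed = 1)
    p <- radresp:::learner_predict(alg, payload, xt)
    expect_length(p, 30)
    expect_true(all(p >= 0 & p <= 1), info = alg)
    # better than chance on separable training data
    expect_gt(roc_auc(p, samp$pcr)$auc, 0.8)
  }
})
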