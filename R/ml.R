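# Hypothesis-free track. DEG selection is deliberately conservative: two
# statistics with different assumptions (an empirical-Bayes moderated t
# and a rank-sum test) are BH-adjusted within every class-balanced
# subsample and a gene is "robust" only when both calls fire in every
# subsample. The robust set is then pruned to decision-making genes by
# recursive importance-based elimination, and six standard classifiers
# are compared in two feature modes under stratified K-fold CV before the
# winner is locked.

#' Quality-check a raw expression matrix
#'
#' Drops genes whose missing fraction exceeds `max_missing`, imputes the
#' remaining missing cells with the gene median, and drops samples whose
#' Pearson correlation with their cohort's median profile falls below
#' `qc_corr_min`. Aborts when more than half the samples fail.
#'
#' @param expr_raw Genes x samples matrix, possibly containing `NA`.
#' @param samples Sample table (used for cohort grouping).
#' @param max_missing Maximum tolerated per-gene missing fraction.
#' @param qc_corr_min Minimum correlation to the cohort median profile.
#' @return List with the clean `expr` and a `report` of removals.
#' @export
quality_check <- function(expr_raw, samples, max_missing = 0.05,
                          qc_corr_min = 0.7) {
  miss_frac <- rowMeans(is.na(expr_raw))
  drop_genes <- rownames(expr_raw)[miss_frac > max_missing]
  expr <- expr_raw[miss_frac <= max_missing, , drop = FALSE]
  if (anyNA(expr)) {
    med <- apply(expr, 1, stats::median, na.rm = TRUE)
    na_idx <- which(is.na(expr), arr.ind = TRUE)
    expr[na_idx] <- med[na_idx[, 1]]
  }
  cohort <- samples$cohort[match(colnames(expr), samples$sample_id)]
  corr <- rep(NA_real_, ncol(expr))
  for (co in unique(cohort)) {
    cols <- which(cohort == co)
    ref <- apply(expr[, cols, drop = FALSE], 1, stats::median)
    corr[cols] <- as.numeric(stats::cor(expr[, cols, drop = FALSE], ref))
  }
  drop_samples <- colnames(expr)[corr < qc_corr_min]
  if (length(drop_samples) > 0.5 * ncol(expr)) {
    abort(sprintf("QC failure: %d/%d samples below correlation %.2f",
                  length(drop_samples), ncol(expr), qc_corr_min),
          "radresp_qc_error")
  }
  keep <- !colnames(expr) %in% drop_samples
  report <- list(dropped_genes = drop_genes, dropped_samples = drop_samples,
                 imputed_cells = sum(is.na(expr_raw[miss_frac <= max_missing, ])),
                 sample_correlation = setNames(corr, colnames(expr)))
  log_stage("quality_check", genes_dropped = length(drop_genes),
            samples_dropped = length(drop_samples))
  list(expr = expression_matrix(expr[, keep, drop = FALSE]), report = report)
}

#' Class-balanced downsampling iterations
#'
#' Each iteration keeps every minority-class sample and draws, without
#' replacement, an equally sized majority-class subset; iterations differ
#' in their majority draws. An already balanced cohort is returned whole
#' in every iteration.
#'
#' @param samples Sample table with non-missing `pcr`.
#' @param n_iter Number of iterations (study default 100).
#' @param seed Integer seed; same seed reproduces the same subsets.
#' @return List of character vectors of sample ids.
#' @export
balance_iterations <- function(samples, n_iter = 100L, seed = 1L) {
  samples <- sample_table(samples, require_pcr = TRUE)
  pos <- samples$sample_id[samples$pcr == 1]
  neg <- samples$sample_id[samples$pcr == 0]
  if (!length(pos) || !length(neg)) {
    abort("both outcome classes required", "radresp_validation_error")
  }
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  if (length(minority) < 2L) abort("need >= 2 minority samples", "radresp_validation_error")
  local_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      draw <- sample(majority, length(minority))
      sort(c(minority, draw))
    })
  })
}

# Inverse of the trigamma function by Newton iteration on 1/x scale
# (the standard approach for EB prior df estimation).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Moderated two-sample t per gene: pooled within-group variances are
# shrunk toward a common prior fitted by moments on the log variances.
moderated_t <- function(x, y) {
  i1 <- which(y == 1); i0 <- which(y == 0)
  n1 <- length(i1); n0 <- length(i0)
  df <- n1 + n0 - 2
  m1 <- rowMeans(x[, i1, drop = FALSE]); m0 <- rowMeans(x[, i0, drop = FALSE])
  s2 <- ((n1 - 1) * row_vars(x[, i1, drop = FALSE]) +
         (n0 - 1) * row_vars(x[, i0, drop = FALSE])) / df
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion of log-variances: infinite prior df, and the
    # arithmetic mean of the sample variances is the MLE of the scale
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_2 + df * s2) / (d0 + df) else
    rep(s0_2, length(s2))
  tstat <- (m1 - m0) / sqrt(s2_post * (1 / n1 + 1 / n0))
  # total df capped at the pooled residual df across genes
  df_total <- min(df + d0, df * sum(ok))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  zero <- s2 == 0 & (m1 - m0) == 0
  tstat[zero] <- 0; p[zero] <- 1
  list(statistic = tstat, p_value = p, df_prior = d0, s2_prior = s0_2)
}

# Vectorised Mann-Whitney test per gene (normal approximation with tie
# correction and continuity correction, matching wilcox.test(exact=FALSE)).
rank_sum <- function(x, y) {
  i1 <- which(y == 1)
  n1 <- length(i1); n0 <- ncol(x) - n1; n <- n1 + n0
  stats_p <- apply(x, 1, function(row) {
    r <- rank(row)
    U <- sum(r[i1]) - n1 * (n1 + 1) / 2
    ties <- table(row)
    sigma2 <- (n1 * n0 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- U - n1 * n0 / 2
    if (sigma2 <= 0) return(c(0, 1))
    zc <- (z - sign(z) * 0.5) / sqrt(sigma2)
    c(zc, 2 * min(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE), 0.5))
  })
  list(statistic = stats_p[1, ], p_value = stats_p[2, ])
}

#' Robust differential-expression selection over balanced subsamples
#'
#' Within every balanced subset a gene is "selected" when both the
#' moderated-t and the rank-sum BH-adjusted p-values are at most
#' `alpha_adj`; the robust set is the intersection over all subsets
#' (selected in every iteration). Zero-variance genes within a subset get
#' statistic 0 / p 1.
#'
#' @param expr Genes x samples matrix (discovery, QC-passed).
#' @param samples Sample table.
#' @param subsets Output of [balance_iterations()].
#' @param alpha_adj BH-adjusted significance threshold, default 0.05.
#' @return data.frame per gene: mean statistics of the two methods,
#'   median adjusted p-values, `n_iterations_selected`, and `robust`
#'   (selected in all iterations).
#' @export
select_degs <- function(expr, samples, subsets, alpha_adj = 0.05) {
  genes <- rownames(expr)
  y_all <- samples$pcr[match(colnames(expr), samples$sample_id)]
  names(y_all) <- colnames(expr)
  N <- length(subsets)
  sel_count <- setNames(rep(0L, length(genes)), genes)
  t_sum <- z_sum <- setNames(rep(0, length(genes)), genes)
  pt_med <- pz_med <- matrix(NA_real_, length(genes), N)
  for (j in seq_len(N)) {
    ids <- subsets[[j]]
    x <- expr[, ids, drop = FALSE]
    y <- y_all[ids]
    mt <- moderated_t(x, y)
    rs <- rank_sum(x, y)
    p_t <- stats::p.adjust(mt$p_value, "BH")
    p_z <- stats::p.adjust(rs$p_value, "BH")
    sel_count <- sel_count + as.integer(p_t <= alpha_adj & p_z <= alpha_adj)
    t_sum <- t_sum + mt$statistic
    z_sum <- z_sum + rs$statistic
    pt_med[, j] <- p_t; pz_med[, j] <- p_z
  }
  data.frame(
    gene = genes,
    mean_moderated_t = t_sum / N,
    mean_ranksum_z = z_sum / N,
    median_adj_p_t = apply(pt_med, 1, stats::median),
    median_adj_p_ranksum = apply(pz_med, 1, stats::median),
    n_iterations_selected = sel_count,
    robust = sel_count == N,
    stringsAsFactors = FALSE, row.names = NULL)
}

# Stratified K-fold assignment, deterministic given seed.
stratified_folds <- function(y, k, seed) {
  local_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Mean stratified K-fold CV accuracy of one algorithm/hyper combination.
cv_accuracy <- function(x, y, algorithm, hyper, k = 10L, seed = 1L,
                        threshold = 0.5) {
  fold <- stratified_folds(y, k, derive_seed(seed, "folds"))
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    payload <- learner_fit(algorithm, x[tr, , drop = FALSE], y[tr], hyper,
                           derive_seed(seed, paste0("fold", f)))
    p <- learner_predict(algorithm, payload, x[!tr, , drop = FALSE])
    mean((p >= threshold) == (y[!tr] == 1))
  }, numeric(1))
  list(mean = mean(accs, na.rm = TRUE), folds = accs)
}

#' Decision-making-gene selection by recursive importance elimination
#'
#' Fits the learner on the current gene set, records its stratified CV
#' accuracy, drops the lowest-importance decile, and repeats down to
#' `floor_min` genes. Returns the smallest recorded set whose CV accuracy
#' is within `tol_acc` of the best. Learners without an importance
#' measure fall back to ranking by absolute moderated-t statistic
#' (logged).
#'
#' @param expr Genes x samples matrix.
#' @param samples Sample table.
#' @param candidate_genes Starting gene set (normally the robust DEGs).
#' @param learner Registry algorithm id, default `"boosted_trees"`.
#' @param seed Integer seed.
#' @param tol_acc Accuracy tolerance for preferring a smaller set.
#' @param floor_min Minimum set size, default 5.
#' @param k Folds for the CV accuracy, default 5.
#' @return Character vector of selected genes, with the elimination
#'   `trace` attached as an attribute.
#' @export
select_dmgs <- function(expr, samples, candidate_genes,
                        learner = "boosted_trees", seed = 1L,
                        tol_acc = 0.01, floor_min = 5L, k = 5L) {
  if (!length(candidate_genes)) abort("no candidate genes", "radresp_validation_error")
  candidate_genes <- intersect(candidate_genes, rownames(expr))
  y <- samples$pcr[match(colnames(expr), samples$sample_id)]
  hyper <- learner_registry()[[learner]]$grid[[1]]
  current <- candidate_genes
  trace <- list()
  round <- 0L
  while (TRUE) {
    round <- round + 1L
    x <- t(expr[current, , drop = FALSE])
    acc <- cv_accuracy(x, y, learner, hyper, k = k,
                       seed = derive_seed(seed, paste0("dmg_cv", round)))
    trace[[round]] <- list(genes = current, accuracy = acc$mean)
    if (length(current) <= floor_min) break
    payload <- learner_fit(learner, x, y, hyper,
                           derive_seed(seed, paste0("dmg_fit", round)))
    imp <- learner_importance(learner, payload, current)
    if (is.null(imp)) {
      log_stage("select_dmgs", fallback = "abs moderated t ranking")
      imp <- abs(moderated_t(expr[current, , drop = FALSE], y)$statistic)
      names(imp) <- current
    }
    n_drop <- max(1L, floor(0.1 * length(current)))
    n_drop <- min(n_drop, length(current) - floor_min)
    if (n_drop < 1L) n_drop <- length(current) - floor_min
    drop <- names(sort(imp))[seq_len(max(n_drop, 1L))]
    current <- setdiff(current, drop)
  }
  accs <- vapply(trace, `[[`, numeric(1), "accuracy")
  sizes <- vapply(trace, function(t) length(t$genes), integer(1))
  ok <- accs >= max(accs) - tol_acc
  best <- which(ok)[which.min(sizes[ok])]
  out <- trace[[best]]$genes
  attr(out, "trace") <- data.frame(round = seq_along(accs), size = sizes,
                                   accuracy = accs)
  out
}

#' Train candidate model configurations and lock the winner
#'
#' Evaluates every requested algorithm in two feature modes (all robust
#' DEGs vs the pruned DMG subset) by stratified K-fold CV accuracy on a
#' class-balanced design (all minority samples plus one seeded majority
#' draw). Hyperparameter grids are searched inside the CV. The winner is
#' the configuration with the highest mean accuracy; ties prefer fewer
#' genes, remaining ties the fixed registry order. The winner is refit on
#' all discovery samples and frozen into a [locked_model()]. A
#' configuration that fails to fit is recorded and excluded.
#'
#' @param expr Genes x samples discovery matrix.
#' @param samples Discovery sample table.
#' @param deg_genes Robust DEG list.
#' @param dmg_genes DMG subset.
#' @param seed Integer seed controlling balancing, folds and fits.
#' @param algorithms Registry algorithms to include (default all six).
#' @param k CV folds, default 10.
#' @return List with `cv_table` (one row per configuration) and `model`
#'   (the locked winner).
#' @export
train_and_select <- function(expr, samples, deg_genes, dmg_genes, seed = 1L,
                             algorithms = names(learner_registry()), k = 10L) {
  if (!length(deg_genes) || !length(dmg_genes)) {
    abort("gene lists must be non-empty", "radresp_validation_error")
  }
  reg <- learner_registry()
  stopifnot(all(algorithms %in% names(reg)))
  balanced_ids <- balance_iterations(samples, n_iter = 1L,
                                     seed = derive_seed(seed, "cv_balance"))[[1]]
  y <- samples$pcr[match(balanced_ids, samples$sample_id)]
  modes <- list(deg = deg_genes, dmg = dmg_genes)
  rows <- list(); fold_acc <- list()
  for (alg in algorithms) {
    for (mode in names(modes)) {
      genes <- intersect(modes[[mode]], rownames(expr))
      x <- t(expr[genes, balanced_ids, drop = FALSE])
      config <- paste0(alg, if (mode == "dmg") "_dmg" else "_deg")
      res <- tryCatch({
        grid_acc <- lapply(seq_along(reg[[alg]]$grid), function(gi) {
          cv_accuracy(x, y, alg, reg[[alg]]$grid[[gi]], k = k,
                      seed = derive_seed(seed, paste0(config, "_g", gi)))
        })
        gi <- which.max(vapply(grid_acc, `[[`, numeric(1), "mean"))
        list(acc = grid_acc[[gi]], hyper = reg[[alg]]$grid[[gi]], ok = TRUE)
      }, error = function(e) {
        warn_log(sprintf("configuration %s failed: %s", config, conditionMessage(e)))
        list(ok = FALSE)
      })
      rows[[config]] <- data.frame(
        config_id = config, algorithm = alg, feature_mode = mode,
        n_genes = length(genes),
        mean_accuracy = if (res$ok) res$acc$mean else NA_real_,
        failed = !res$ok, stringsAsFactors = FALSE)
      if (res$ok) {
        fold_acc[[config]] <- res$acc$folds
        rows[[config]]$hyper <- I(list(res$hyper))
      } else rows[[config]]$hyper <- I(list(NULL))
    }
  }
  cv_table <- do.call(rbind, rows)
  rownames(cv_table) <- NULL
  ok <- !cv_table$failed
  if (!any(ok)) abort("every configuration failed", "radresp_training_error")
  cand <- cv_table[ok, ]
  # highest accuracy, then fewest genes, then fixed algorithm order
  alg_rank <- match(cand$algorithm, names(reg))
  ord <- order(-cand$mean_accuracy, cand$n_genes, alg_rank,
               match(cand$feature_mode, c("deg", "dmg")))
  win <- cand[ord[1], ]
  win_genes <- intersect(modes[[win$feature_mode]], rownames(expr))
  x_full <- t(expr[win_genes, , drop = FALSE])
  y_full <- samples$pcr[match(rownames(x_full), samples$sample_id)]
  payload <- learner_fit(win$algorithm, x_full, y_full, win$hyper[[1]],
                         derive_seed(seed, "final_fit"))
  model <- locked_model(win$algorithm, win_genes, win$hyper[[1]], payload,
                        training_seed = seed,
                        cv_accuracy = win$mean_accuracy,
                        created_from = sprintf("train_and_select k=%d config=%s",
                                               k, win$config_id))
  log_stage("train_and_select", winner = win$config_id,
            accuracy = round(win$mean_accuracy, 3), genes = win$n_genes)
  list(cv_table = cv_table, fold_accuracies = fold_acc, model = model)
}
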