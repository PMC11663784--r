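# Biological characterisation of a locked predictor: preranked GSEA of
# predicted-vs-actual contrasts, per-gene regression against the
# candidate-track features pooled by meta-analysis, and cell-type
# specificity from a sorted-population reference.

#' Rank genes by a two-class contrast
#'
#' Metric is the signed standardised mean difference (class 1 minus
#' class 0, divided by the pooled SD), returned in descending order with
#' ties broken by gene id (logged).
#'
#' @param expr Genes x samples matrix.
#' @param class_labels Binary 0/1 vector aligned to columns (e.g.
#'   predicted or actual outcome).
#' @return data.frame with `gene` and `metric`, sorted descending.
#' @export
rank_genes <- function(expr, class_labels) {
  y <- as.integer(class_labels)
  if (length(unique(y)) < 2L) abort("both classes required", "radresp_validation_error")
  i1 <- y == 1; i0 <- y == 0
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(expr[, i1, drop = FALSE]); m0 <- rowMeans(expr[, i0, drop = FALSE])
  sp <- sqrt(((n1 - 1) * row_vars(expr[, i1, drop = FALSE]) +
              (n0 - 1) * row_vars(expr[, i0, drop = FALSE])) / (n1 + n0 - 2))
  metric <- (m1 - m0) / sp
  metric[sp == 0] <- 0
  ord <- order(-metric, rownames(expr))
  if (anyDuplicated(metric)) log_stage("rank_genes", ties_broken_by = "gene id")
  data.frame(gene = rownames(expr)[ord], metric = metric[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Weighted Kolmogorov-Smirnov enrichment score for one set given hit
# positions in the ranking; O(set size) per evaluation.
es_from_positions <- function(pos, weights_abs_p, N, total_weight) {
  k <- length(pos)
  ord <- order(pos)
  pos <- pos[ord]
  w <- weights_abs_p[ord]
  cw <- cumsum(w) / total_weight
  miss_den <- N - k
  # running sum evaluated just after each hit and just before each hit
  after <- cw - (pos - seq_len(k)) / miss_den
  before <- c(0, cw[-k]) - (pos - 1 - (seq_len(k) - 1)) / miss_den
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic over a ranked gene
#' list (weight exponent `weight_p`; 0 gives the classic unweighted KS
#' statistic). The null is by gene-label permutation: random sets of the
#' same size drawn from the ranking. NES is ES divided by the mean
#' absolute null ES of matching sign; nominal p-values are one-sided
#' within sign with the add-one convention, and FDR is BH across sets.
#' Sets intersecting the ranking in fewer than `min_size` genes are
#' skipped with a warning.
#'
#' @param ranked data.frame from [rank_genes()] (or a named metric vector
#'   sorted descending).
#' @param sets Named list of gene sets.
#' @param weight_p Weight exponent on |metric|, default 1.
#' @param n_perm Gene-permutation draws, default 1000.
#' @param seed Integer seed.
#' @param min_size Minimum set overlap with the ranking, default 5.
#' @return data.frame per retained set: `set`, `size`, `es`, `nes`,
#'   `p_value`, `fdr`, `direction`, `leading_edge` (list column).
#' @export
gsea_preranked <- function(ranked, sets, weight_p = 1, n_perm = 1000L,
                           seed = 1L, min_size = 5L) {
  if (is.data.frame(ranked)) {
    metric <- setNames(ranked$metric, ranked$gene)
  } else metric <- ranked
  if (is.unsorted(rev(metric))) {
    metric <- sort(metric, decreasing = TRUE)
  }
  genes <- names(metric)
  N <- length(genes)
  wts <- abs(metric)^weight_p

  rows <- list()
  for (nm in names(sets)) {
    pos <- which(genes %in% sets[[nm]])
    k <- length(pos)
    if (k < min_size || k >= N) {
      warn_log(paste0("set '", nm, "' skipped (overlap ", k, ")"))
      next
    }
    tw <- sum(wts[pos])
    es <- if (tw == 0) 0 else es_from_positions(pos, wts[pos], N, tw)
    null_es <- local_seed(derive_seed(seed, nm), {
      vapply(seq_len(n_perm), function(b) {
        rp <- sample.int(N, k)
        twb <- sum(wts[rp])
        if (twb == 0) 0 else es_from_positions(rp, wts[rp], N, twb)
      }, numeric(1))
    })
    same <- null_es[sign(null_es) == sign(es)]
    p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    denom <- mean(abs(same))
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    # leading edge: hits at or before the running-sum extremum (positive
    # ES) or at/after it (negative ES)
    pos_sorted <- sort(pos)
    cw <- cumsum(wts[pos_sorted]) / sum(wts[pos_sorted])
    run <- cw - (pos_sorted - seq_along(pos_sorted)) / (N - k)
    le <- if (es >= 0) {
      genes[pos_sorted[seq_len(which.max(run))]]
    } else {
      pre <- c(0, cw[-k]) - (pos_sorted - 1 - (seq_along(pos_sorted) - 1)) / (N - k)
      genes[pos_sorted[seq(which.min(pre), k)]]
    }
    rows[[nm]] <- data.frame(
      set = nm, size = k, es = es, nes = nes, p_value = p,
      direction = if (es >= 0) "up_in_class1" else "up_in_class0",
      leading_edge = I(list(le)), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out[, c("set", "size", "es", "nes", "p_value", "fdr", "direction",
          "leading_edge")]
}

#' Concordance between two enrichment analyses
#'
#' @param enrich_a,enrich_b Results of [gsea_preranked()] over the same
#'   collection (e.g. predicted-status vs actual-status contrasts).
#' @param fdr_cut Significance cut on the BH FDR, default 0.25.
#' @return List with `shared` (significant in both, with sign agreement
#'   per set), `a_only`, `b_only`, and `sign_agreement` (fraction of
#'   shared sets with equal ES direction).
#' @export
concordance_of_contrasts <- function(enrich_a, enrich_b, fdr_cut = 0.25) {
  sig_a <- enrich_a$set[enrich_a$fdr <= fdr_cut]
  sig_b <- enrich_b$set[enrich_b$fdr <= fdr_cut]
  shared <- intersect(sig_a, sig_b)
  agree <- vapply(shared, function(s) {
    sign(enrich_a$es[enrich_a$set == s]) == sign(enrich_b$es[enrich_b$set == s])
  }, logical(1))
  list(shared = data.frame(set = shared, same_direction = agree,
                           stringsAsFactors = FALSE, row.names = NULL),
       a_only = setdiff(sig_a, sig_b), b_only = setdiff(sig_b, sig_a),
       sign_agreement = if (length(shared)) mean(agree) else NA_real_)
}

#' Per-gene association with a feature score, meta-analysed over cohorts
#'
#' For every cohort, each gene's expression is regressed on the feature
#' score by ordinary least squares; the per-cohort slopes are pooled by
#' inverse-variance meta-analysis ([meta_analyse()]) with heterogeneity.
#' Cohorts with a constant score are excluded for that feature with a
#' warning.
#'
#' @param expr_list Named list of genes x samples matrices, one per
#'   cohort.
#' @param score_list Named list (same cohort names) of named lists /
#'   data.frames of per-sample feature scores.
#' @param genes Genes to analyse.
#' @param features Feature names to analyse (default: all shared).
#' @return data.frame, one row per (gene, feature), with the pooled
#'   estimates and heterogeneity statistics.
#' @export
gene_feature_meta <- function(expr_list, score_list, genes, features = NULL) {
  stopifnot(identical(names(expr_list), names(score_list)))
  features <- features %||% Reduce(intersect, lapply(score_list, names))
  rows <- list()
  for (f in features) {
    for (g in genes) {
      betas <- c(); ses <- c()
      for (co in names(expr_list)) {
        sc <- score_list[[co]][[f]]
        if (is.null(sc) || stats::sd(sc, na.rm = TRUE) == 0) {
          warn_log(paste0("feature '", f, "' constant in cohort '", co,
                          "'; cohort excluded"))
          next
        }
        if (!g %in% rownames(expr_list[[co]])) next
        yv <- expr_list[[co]][g, names(sc)]
        fit <- stats::lm(yv ~ sc)
        cf <- stats::coef(summary(fit))
        betas <- c(betas, cf["sc", "Estimate"])
        ses <- c(ses, cf["sc", "Std. Error"])
      }
      if (!length(betas)) next
      res <- meta_analyse(betas, ses, label = paste(g, f, sep = ":"))
      res$gene <- g; res$feature <- f
      rows[[paste(g, f)]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type specificity from a sorted-population reference
#'
#' A gene is assigned to the cell type with the highest linear-scale
#' reference expression when the fold-change over the second-highest type
#' is at least `fc_threshold` (boundary inclusive); otherwise `"none"`.
#' Genes absent from the reference get `"none"` with a warning.
#'
#' @param reference Genes x cell-types matrix of linear-scale mean
#'   expression per sorted population (canonically epithelial, leucocyte,
#'   endothelial, fibroblast).
#' @param genes Genes to assign.
#' @param fc_threshold Minimum top/second fold-change, default 2.
#' @return data.frame with `gene`, `assigned`, `fold_change`.
#' @export
assign_cell_types <- function(reference, genes, fc_threshold = 2) {
  stopifnot(is.matrix(reference), ncol(reference) >= 2)
  out <- lapply(genes, function(g) {
    if (!g %in% rownames(reference)) {
      warn_log(paste0("gene '", g, "' absent from reference"))
      return(data.frame(gene = g, assigned = "none", fold_change = NA_real_,
                        stringsAsFactors = FALSE))
    }
    v <- sort(reference[g, ], decreasing = TRUE)
    fc <- unname(v[1] / v[2])
    data.frame(gene = g,
               assigned = if (is.finite(fc) && fc >= fc_threshold)
                 names(v)[1] else "none",
               fold_change = fc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
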