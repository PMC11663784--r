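# External validation of a locked model: confusion metrics and AUC on a
# batch-corrected validation cohort, a size-matched random-geneset
# permutation null, and comparison against user-supplied published
# signatures. The locked model is applied, never refit; a hash check
# asserts it.

#' Validate a locked model on an external cohort
#'
#' @param model A [locked_model()]; all its genes must be present.
#' @param expr_corrected Batch-corrected genes x samples validation
#'   matrix.
#' @param samples Sample table with non-missing `pcr` for scored samples.
#' @param threshold Classification threshold on the model score scale
#'   (default 0.5; recorded in the report).
#' @return A `validation_report`: confusion counts, sensitivity,
#'   specificity, accuracy, AUC with DeLong 95% CI, scores, threshold,
#'   and the model hash (identical before and after scoring).
#' @export
validate_model <- function(model, expr_corrected, samples, threshold = 0.5) {
  hash_before <- model_hash(model)
  scores <- predict(model, expr_corrected)
  y <- samples$pcr[match(names(scores), samples$sample_id)]
  if (anyNA(y)) abort("missing outcome for validation samples",
                      "radresp_validation_error")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  out <- list(TP = tp, FP = fp, TN = tn, FN = fn,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              accuracy = (tp + tn) / length(y),
              threshold = threshold, scores = scores,
              model_hash = hash_before)
  if (length(unique(y)) < 2L) {
    warn_log("one outcome class absent; AUC not computed")
    out$auc <- NA_real_; out$auc_ci <- c(NA_real_, NA_real_)
  } else {
    out$auc <- roc_auc(scores, y)$auc
    ci <- suppressMessages(pROC::ci.auc(pROC::roc(y, as.numeric(scores),
                                                  direction = "<", quiet = TRUE),
                                        method = "delong"))
    out$auc_ci <- c(ci[1], ci[3])
  }
  stopifnot(identical(model_hash(model), hash_before))
  structure(out, class = "validation_report")
}

#' Random-geneset permutation null for a validation AUC
#'
#' Draws `B` gene sets of size `m` without replacement from the
#' universe, evaluates each on the validation cohort with the same
#' modelling recipe used for the observed model (refitting on discovery
#' per draw, or a cheaper orientation-aware mean-z score when
#' `mode = "score_only"`), and reports the add-one empirical p-value
#' `p = (r + 1) / (B + 1)` with `r` the number of draws whose AUC is at
#' least the observed one (both the `>=` and the strict `>` conventions
#' are returned).
#'
#' @param expr Genes x samples corrected matrix covering discovery and
#'   validation samples.
#' @param samples Sample table with non-missing `pcr`.
#' @param discovery_ids,validation_ids Sample id vectors.
#' @param observed_auc AUC of the locked model on the validation cohort.
#' @param m Gene-set size (the locked model's gene count).
#' @param B Number of draws.
#' @param universe Gene universe to draw from; default every gene in
#'   `expr` (the QC-passing universe).
#' @param seed Integer seed.
#' @param mode `"refit"` or `"score_only"`.
#' @param recipe For `"refit"`: list with `algorithm` and `hyper`.
#' @return List with `null_auc` (length B), `p` (`>=` convention),
#'   `p_strict`, `m`, `B`, `universe_size`, `seed`, `mode`.
#' @export
permutation_null <- function(expr, samples, discovery_ids, validation_ids,
                             observed_auc, m, B = 1000L, universe = NULL,
                             seed = 1L, mode = c("refit", "score_only"),
                             recipe = list(algorithm = "boosted_trees",
                                           hyper = list(nrounds = 50,
                                                        max_depth = 2))) {
  mode <- match.arg(mode)
  universe <- universe %||% rownames(expr)
  if (m > length(universe)) abort("set size exceeds universe", "radresp_validation_error")
  if (B < 1) abort("B must be >= 1", "radresp_validation_error")
  y <- setNames(samples$pcr, samples$sample_id)
  y_d <- y[discovery_ids]; y_v <- y[validation_ids]
  draws <- local_seed(seed, {
    lapply(seq_len(B), function(b) sample(universe, m))
  })
  null_auc <- vapply(seq_along(draws), function(b) {
    genes <- draws[[b]]
    if (mode == "refit") {
      x_d <- t(expr[genes, discovery_ids, drop = FALSE])
      payload <- learner_fit(recipe$algorithm, x_d, as.numeric(y_d),
                             recipe$hyper, derive_seed(seed, paste0("draw", b)))
      p <- learner_predict(recipe$algorithm, payload,
                           t(expr[genes, validation_ids, drop = FALSE]))
    } else {
      # orientation-aware mean z: each gene signed by its discovery
      # class-mean difference, scored on the validation cohort
      x_d <- expr[genes, discovery_ids, drop = FALSE]
      sgn <- sign(rowMeans(x_d[, y_d == 1, drop = FALSE]) -
                  rowMeans(x_d[, y_d == 0, drop = FALSE]))
      sgn[sgn == 0] <- 1
      x_v <- expr[genes, validation_ids, drop = FALSE]
      mu <- rowMeans(x_v); sdv <- sqrt(row_vars(x_v)); sdv[sdv == 0] <- 1
      p <- colMeans(sgn * (x_v - mu) / sdv)
    }
    roc_auc(p, y_v)$auc
  }, numeric(1))
  r_ge <- sum(null_auc >= observed_auc)
  r_gt <- sum(null_auc > observed_auc)
  list(null_auc = null_auc, p = (r_ge + 1) / (B + 1),
       p_strict = (r_gt + 1) / (B + 1), m = m, B = B,
       universe_size = length(universe), seed = seed, mode = mode,
       observed_auc = observed_auc)
}

#' Compare candidate and published signatures on one cohort
#'
#' Scores every signature, reports the Pearson correlation matrix of the
#' per-sample scores, and per signature the adjusted logistic odds ratio,
#' p-value and AUC for the outcome, sorted by AUC. Unscorable signatures
#' (no genes present) are excluded with a warning.
#'
#' @param signature_list List of [signature_def()] objects.
#' @param expr_corrected Genes x samples matrix.
#' @param samples Sample table with non-missing `pcr`.
#' @param adjust Covariates for the logistic fit.
#' @param method Scoring method passed to [score_signature()].
#' @return List with `scores` (samples x signatures), `correlations`, and
#'   `table` (per-signature OR, p, AUC, sorted by AUC).
#' @export
compare_signatures <- function(signature_list, expr_corrected, samples,
                               adjust = c("t_stage", "n_stage"),
                               method = "mean_z") {
  scored <- list()
  for (sig in signature_list) {
    s <- tryCatch(score_signature(expr_corrected, sig, method = method),
                  radresp_scoring_error = function(e) {
                    warn_log(paste0("signature '", sig$name, "' unscorable; excluded"))
                    NULL
                  })
    if (!is.null(s)) scored[[sig$name]] <- s
  }
  if (!length(scored)) abort("no scorable signatures", "radresp_scoring_error")
  scores <- do.call(cbind, scored)
  y <- samples$pcr[match(rownames(scores), samples$sample_id)]
  tab <- do.call(rbind, lapply(colnames(scores), function(nm) {
    res <- univariable_adjusted(setNames(scores[, nm], rownames(scores)),
                                samples, adjust = adjust, feature = nm)
    res$auc <- roc_auc(scores[, nm], y)$auc
    res
  }))
  tab <- tab[order(-tab$auc), ]
  rownames(tab) <- NULL
  list(scores = scores, correlations = stats::cor(scores), table = tab)
}
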