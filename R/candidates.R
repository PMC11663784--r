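# Hypothesis-based track: candidate features are tested one at a time by
# logistic regression adjusted for cohort and baseline T/N stage, pruned
# by backward stepwise selection under a likelihood-ratio criterion, and
# the survivors combined into a single biology-only compound score.

build_covariate_frame <- function(samples, adjust,
                                  stage_encoding = c("ordinal", "categorical")) {
  stage_encoding <- match.arg(stage_encoding)
  covs <- lapply(adjust, function(a) {
    v <- samples[[a]]
    if (is.null(v)) abort(paste0("unknown covariate: ", a), "radresp_validation_error")
    if (a %in% c("t_stage", "n_stage") && stage_encoding == "ordinal") {
      as.numeric(v)
    } else if (a %in% c("cohort", "batch") || stage_encoding == "categorical") {
      factor(v)
    } else as.numeric(v)
  })
  names(covs) <- adjust
  if (!length(covs)) return(data.frame(row.names = seq_len(nrow(samples))))
  as.data.frame(covs, stringsAsFactors = FALSE, optional = TRUE)
}

fit_logistic <- function(df) {
  # drop single-level factors (e.g. one cohort only) before fitting
  keep <- vapply(df, function(v) !is.factor(v) || nlevels(droplevels(v)) > 1,
                 logical(1))
  keep["pcr"] <- TRUE
  stats::glm(pcr ~ ., data = df[, keep, drop = FALSE], family = stats::binomial())
}

is_separated <- function(fit) {
  p <- stats::fitted(fit)
  all(p < 1e-8 | p > 1 - 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
}

#' Adjusted univariable logistic regression of outcome on one feature
#'
#' Maximum-likelihood fit of `pcr ~ score + covariates` over complete
#' cases (dropped rows are counted), with Wald confidence interval and
#' p-value for the feature. Perfect separation is flagged and reported
#' with an infinite-OR sentinel rather than silently penalised; fewer
#' than 10 events triggers a warning.
#'
#' @param score Named numeric (or binary) vector of per-sample feature
#'   values; names must match `samples$sample_id`.
#' @param samples Sample table with non-missing `pcr` for used rows.
#' @param adjust Covariate names (subset of sample-table columns);
#'   `character(0)` for an unadjusted fit.
#' @param stage_encoding `"ordinal"` (numeric stages, default) or
#'   `"categorical"`.
#' @param feature Feature name for the report.
#' @return One-row data.frame: `feature`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `n_used`, `adjusted`, `separated`.
#' @export
univariable_adjusted <- function(score, samples,
                                 adjust = c("cohort", "t_stage", "n_stage"),
                                 stage_encoding = "ordinal",
                                 feature = deparse(substitute(score))) {
  idx <- match(samples$sample_id, names(score))
  if (anyNA(idx)) abort("score is missing samples", "radresp_validation_error")
  df <- cbind(data.frame(pcr = samples$pcr, score = as.numeric(score[idx])),
              build_covariate_frame(samples, adjust, stage_encoding))
  cc <- stats::complete.cases(df)
  if (!all(cc)) log_stage("univariable_adjusted", dropped = sum(!cc))
  df <- df[cc, , drop = FALSE]
  if (stats::sd(df$score) == 0) {
    abort(paste0("feature '", feature, "' is constant"), "radresp_scoring_error")
  }
  if (sum(df$pcr) < 10) warn_log("fewer than 10 events in adjusted model")
  fit <- fit_logistic(df)
  sep <- is_separated(fit)
  b <- stats::coef(summary(fit))["score", ]
  or <- exp(b["Estimate"])
  ci <- exp(b["Estimate"] + c(-1, 1) * stats::qnorm(0.975) * b["Std. Error"])
  if (sep) {
    warn_log(paste0("perfect separation suspected for '", feature,
                    "'; odds ratio reported as infinite sentinel"))
    or <- Inf; ci <- c(NA_real_, NA_real_)
  }
  data.frame(feature = feature, odds_ratio = unname(or),
             ci_low = ci[1], ci_high = ci[2],
             p_value = unname(b["Pr(>|z|)"]), n_used = nrow(df),
             adjusted = paste(adjust, collapse = "+"), separated = sep,
             stringsAsFactors = FALSE)
}

#' Backward stepwise logistic selection under a likelihood-ratio criterion
#'
#' Starting from the full model of all features plus forced covariates,
#' the feature with the largest likelihood-ratio p-value above
#' `alpha_remove` is removed, repeatedly, until every retained feature has
#' LR p <= `alpha_remove`. Covariates are never eliminated. Ties are
#' broken by column order (logged), so the path is deterministic given
#' input order. Eliminating every feature is a valid outcome (empty model
#' with a warning).
#'
#' @param features Samples x features numeric matrix (rownames = sample
#'   ids) of candidate scores.
#' @param samples Sample table.
#' @param adjust Forced covariates.
#' @param alpha_remove Removal threshold on the LR p-value, default 0.05.
#' @param stage_encoding See [univariable_adjusted()].
#' @return A `stepwise_model`: `retained`, `coefficients`, `intercept`,
#'   `log_likelihood`, `trace` (feature, p_value, step), `fit`.
#' @export
backward_stepwise <- function(features, samples,
                              adjust = c("cohort", "t_stage", "n_stage"),
                              alpha_remove = 0.05, stage_encoding = "ordinal") {
  stopifnot(is.matrix(features) || is.data.frame(features))
  features <- as.matrix(features)
  idx <- match(samples$sample_id, rownames(features))
  if (anyNA(idx)) abort("features missing samples", "radresp_validation_error")
  covdf <- build_covariate_frame(samples, adjust, stage_encoding)
  base <- cbind(data.frame(pcr = samples$pcr), covdf)
  current <- colnames(features)
  trace <- data.frame(feature = character(0), p_value = numeric(0),
                      step = integer(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    df <- cbind(base, as.data.frame(features[idx, current, drop = FALSE]))
    cc <- stats::complete.cases(df)
    full <- fit_logistic(df[cc, , drop = FALSE])
    if (!length(current)) break
    pvals <- vapply(current, function(f) {
      red <- fit_logistic(df[cc, setdiff(names(df), f), drop = FALSE])
      stat <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(red)))
      stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which(pvals == max(pvals))[1]  # ties: first column order
    if (length(which(pvals == max(pvals))) > 1) {
      log_stage("backward_stepwise", tie_broken_on = current[worst])
    }
    if (pvals[worst] <= alpha_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(feature = current[worst],
                                     p_value = unname(pvals[worst]),
                                     step = step, stringsAsFactors = FALSE))
    current <- current[-worst]
  }
  if (!length(current)) warn_log("all features eliminated; empty stepwise model")
  df <- cbind(base, as.data.frame(features[idx, current, drop = FALSE]))
  cc <- stats::complete.cases(df)
  fit <- fit_logistic(df[cc, , drop = FALSE])
  cf <- stats::coef(fit)
  structure(list(retained = current,
                 coefficients = cf[setdiff(names(cf), "(Intercept)")],
                 intercept = unname(cf["(Intercept)"]),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 trace = trace, alpha_remove = alpha_remove, fit = fit),
            class = "stepwise_model")
}

#' Biology-only compound score from a stepwise model
#'
#' The linear predictor restricted to the retained biological features
#' (covariate terms excluded): `intercept + sum(beta_f * score_f)`. A
#' monotone transform of the model's probability when covariates are held
#' fixed, so ROC analysis on it reflects the biology alone.
#'
#' @param model A `stepwise_model`.
#' @param scores Samples x features matrix containing every retained
#'   feature.
#' @param include_intercept Include the model intercept (default `TRUE`;
#'   rank-invariant either way).
#' @return Named numeric vector per sample.
#' @export
compound_score <- function(model, scores, include_intercept = TRUE) {
  stopifnot(inherits(model, "stepwise_model"))
  scores <- as.matrix(scores)
  missing <- setdiff(model$retained, colnames(scores))
  if (length(missing)) {
    abort(paste0("missing feature columns: ", paste(missing, collapse = ", ")),
          "radresp_validation_error")
  }
  beta <- model$coefficients[model$retained]
  out <- if (length(model$retained)) {
    as.numeric(scores[, model$retained, drop = FALSE] %*% beta)
  } else rep(0, nrow(scores))
  if (include_intercept) out <- out + model$intercept
  setNames(out, rownames(scores))
}

#' Mann-Whitney ROC curve and AUC
#'
#' AUC equals the Mann-Whitney U statistic divided by `n1 * n0`; tied
#' score pairs contribute 1/2, so a constant score yields AUC 0.5 by the
#' tie convention. Also returns the full ROC polyline.
#'
#' @param score Numeric scores (higher = more class-1-like).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return List with `auc` and `roc` (data.frame of fpr, tpr, threshold).
#' @export
roc_auc <- function(score, labels) {
  labels <- as.integer(labels)
  if (length(score) != length(labels) || anyNA(score) || anyNA(labels)) {
    abort("score/labels must be complete and aligned", "radresp_validation_error")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes required", "radresp_validation_error")
  r <- rank(score)  # midranks handle ties with the 1/2 convention
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(score, decreasing = TRUE)
  thr <- unique(score[ord])
  tpr <- vapply(thr, function(t) sum(labels == 1 & score >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(labels == 0 & score >= t) / n0, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}

#' Likelihood-ratio test between nested logistic models
#'
#' @param null_model,full_model Fitted `glm` objects on the same rows;
#'   the null model's terms must be a subset of the full model's.
#' @return List with `statistic` (`2 * (ll_full - ll_null)`), `df`
#'   (parameter difference) and `p_value` (chi-square upper tail; 1 when
#'   the models coincide).
#' @export
likelihood_ratio_test <- function(null_model, full_model) {
  if (stats::nobs(null_model) != stats::nobs(full_model)) {
    abort("models fitted on different rows", "radresp_validation_error")
  }
  n0 <- names(stats::coef(null_model)); n1 <- names(stats::coef(full_model))
  if (!all(n0 %in% n1)) abort("models are not nested", "radresp_validation_error")
  stat <- 2 * (as.numeric(stats::logLik(full_model)) -
               as.numeric(stats::logLik(null_model)))
  df <- length(n1) - length(n0)
  p <- if (df == 0) 1 else stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  list(statistic = max(stat, 0), df = df, p_value = p)
}

#' Inverse-variance meta-analysis with heterogeneity
#'
#' Fixed-effect pooling of per-cohort estimates, Cochran's Q,
#' `I2 = max(0, (Q - df)/Q) * 100`, and (for k >= 2) DerSimonian-Laird
#' random-effects pooling. A single cohort is returned as its own pooled
#' estimate with Q = 0, I2 = 0.
#'
#' @param beta Per-cohort effect estimates.
#' @param se Matching standard errors (> 0).
#' @param label Optional feature/gene label.
#' @return One-row data.frame: pooled fixed-effect `beta`/`se`/`p`, `Q`,
#'   `I2`, random-effects `beta_re`/`se_re`/`tau2`, and `k`.
#' @export
meta_analyse <- function(beta, se, label = NA_character_) {
  k <- length(beta)
  if (k == 0) abort("no cohorts to pool", "radresp_validation_error")
  if (length(se) != k || any(se <= 0)) {
    abort("se must match beta and be positive", "radresp_validation_error")
  }
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  Q <- if (k > 1) sum(w * (beta - pooled)^2) else 0
  df <- k - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  if (k >= 2) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    wr <- 1 / (se^2 + tau2)
    beta_re <- sum(wr * beta) / sum(wr)
    se_re <- sqrt(1 / sum(wr))
  } else {
    tau2 <- 0; beta_re <- pooled; se_re <- pooled_se
  }
  data.frame(label = label, k = k, beta = pooled, se = pooled_se,
             p = 2 * stats::pnorm(-abs(pooled / pooled_se)),
             Q = Q, I2 = I2, tau2 = tau2, beta_re = beta_re, se_re = se_re,
             p_re = 2 * stats::pnorm(-abs(beta_re / se_re)),
             stringsAsFactors = FALSE)
}
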