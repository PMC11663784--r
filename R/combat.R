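# Native parametric empirical-Bayes location/scale batch adjustment.
# Per gene the data are standardised by a covariate-adjusted grand mean
# and pooled variance; per-(gene,batch) location and scale estimates are
# shrunk toward their across-gene priors (normal prior on locations,
# inverse-gamma on scales, hyperparameters by method of moments) via the
# usual fixed-point iteration, then removed. "Supervised" mode adds the
# outcome to the covariate design so the estimated pCR effect is
# protected from (and re-imposed after) the correction; "agnostic" mode
# never sees the outcome.

eb_postmean <- function(g_hat, g_bar, n, d_star, t2) {
  (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
}

eb_postvar <- function(sum2, n, a, b) {
  (0.5 * sum2 + b) / (n / 2 + a - 1)
}

# Fixed-point solution of the EB posterior equations, one batch at a time.
eb_fixed_point <- function(s_batch, g_hat, d_hat, g_bar, t2, a, b,
                           tol = 1e-4, max_iter = 1000L) {
  n <- ncol(s_batch)
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- eb_postmean(g_hat, g_bar, n, d_old, t2)
    sum2 <- rowSums((s_batch - g_new)^2)
    d_new <- eb_postvar(sum2, n, a, b)
    change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
    g_old <- g_new; d_old <- d_new
    if (is.finite(change) && change < tol) break
  }
  list(gamma_star = g_new, delta_star = d_new, iterations = it)
}

#' Fit an empirical-Bayes batch-correction model
#'
#' @param expr Genes x samples matrix covering every sample in `samples`.
#' @param samples Sample table supplying `batch` (and `pcr` for
#'   supervised mode) per sample.
#' @param mode `"supervised"` (outcome in the covariate design) or
#'   `"agnostic"` (outcome never disclosed).
#' @param covariates Additional sample-table columns to protect in the
#'   design (e.g. `"t_stage"`); default none.
#' @param tol,max_iter Fixed-point convergence control for the EB
#'   posterior equations (maximum relative parameter change).
#' @return A `combat_model` containing the shrunk per-(gene,batch)
#'   location (`gamma_star`) and scale (`delta_star`) estimates, the
#'   standardisation moments, per-sample reference means, and the
#'   corrected training matrix in `$corrected`.
#' @export
fit_combat <- function(expr, samples, mode = c("supervised", "agnostic"),
                       covariates = NULL, tol = 1e-4, max_iter = 1000L) {
  mode <- match.arg(mode)
  idx <- match(colnames(expr), samples$sample_id)
  if (anyNA(idx)) abort("samples table missing expression samples",
                        "radresp_validation_error")
  samples <- samples[idx, , drop = FALSE]
  batch <- factor(samples$batch)
  n_array <- ncol(expr)
  n_batches <- table(batch)
  if (any(n_batches < 2)) {
    abort("every batch needs at least 2 samples", "radresp_validation_error")
  }
  if (nlevels(batch) == 1L) {
    # single batch: identity correction
    return(structure(list(
      genes = rownames(expr), batches = levels(batch), mode = mode,
      single_batch = TRUE, samples = samples$sample_id,
      corrected = expr), class = "combat_model"))
  }
  covs <- covariates
  if (mode == "supervised") {
    if (anyNA(samples$pcr)) {
      abort("supervised correction requires non-missing pcr", "radresp_validation_error")
    }
    covs <- union("pcr", covs)
  }
  batchmod <- stats::model.matrix(~ 0 + batch)
  mod <- NULL
  if (length(covs)) {
    covdf <- as.data.frame(lapply(samples[covs], as.numeric))
    mod <- stats::model.matrix(~ ., data = covdf)[, -1, drop = FALSE]
  }
  design <- cbind(batchmod, mod)
  if (qr(design)$rank < ncol(design)) {
    abort("covariates confounded with batch", "radresp_validation_error")
  }

  nb <- nlevels(batch)
  dat <- expr
  B_hat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand_mean <- as.numeric(crossprod(as.numeric(n_batches) / n_array,
                                     B_hat[seq_len(nb), , drop = FALSE]))
  resid <- dat - t(design %*% B_hat)
  var_pooled <- rowSums(resid^2) / n_array
  if (any(var_pooled <= 0)) {
    abort("zero pooled variance; remove constant genes first",
          "radresp_validation_error")
  }
  stand_mean <- matrix(grand_mean, nrow(dat), n_array)
  if (!is.null(mod)) {
    tmp <- design; tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  gamma_star <- delta_star <- matrix(NA_real_, nb, nrow(dat),
                                     dimnames = list(levels(batch), rownames(dat)))
  for (i in seq_len(nb)) {
    cols <- which(batch == levels(batch)[i])
    sb <- s_data[, cols, drop = FALSE]
    g_hat <- rowMeans(sb)
    d_hat <- row_vars(sb)
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a <- (2 * s2 + m^2) / s2
    b <- (m * s2 + m^3) / s2
    sol <- eb_fixed_point(sb, g_hat, d_hat, g_bar, t2, a, b,
                          tol = tol, max_iter = max_iter)
    gamma_star[i, ] <- sol$gamma_star
    delta_star[i, ] <- sol$delta_star
  }

  bayes <- s_data
  for (i in seq_len(nb)) {
    cols <- which(batch == levels(batch)[i])
    bayes[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta_star[i, ])
  }
  corrected <- bayes * sqrt(var_pooled) + stand_mean
  dimnames(corrected) <- dimnames(expr)

  structure(list(
    genes = rownames(expr), batches = levels(batch), mode = mode,
    single_batch = FALSE, covariates = covs %||% character(0),
    grand_mean = setNames(grand_mean, rownames(expr)),
    var_pooled = setNames(var_pooled, rownames(expr)),
    gamma_star = gamma_star, delta_star = delta_star,
    stand_mean = stand_mean, samples = samples$sample_id,
    sample_batch = setNames(as.character(batch), samples$sample_id),
    corrected = corrected), class = "combat_model")
}

#' Apply a fitted batch-correction model
#'
#' Corrects a matrix of samples whose batch labels are known to the
#' model. Training samples reuse their stored covariate-adjusted
#' reference means (so the fit's corrected output is reproduced exactly);
#' unseen samples of a known batch are standardised against the grand
#' mean alone.
#'
#' @param model A `combat_model`.
#' @param expr Genes x samples matrix; genes must be a subset of the
#'   model's genes.
#' @param batch Optional named character vector giving batch labels for
#'   samples not seen at fit time.
#' @return Corrected matrix of the same shape.
#' @export
apply_combat <- function(model, expr, batch = NULL) {
  stopifnot(inherits(model, "combat_model"))
  if (!all(rownames(expr) %in% model$genes)) {
    abort("expression genes not covered by correction model",
          "radresp_validation_error")
  }
  if (model$single_batch) return(expr)
  g <- rownames(expr)
  gi <- match(g, model$genes)
  labels <- setNames(model$sample_batch[colnames(expr)], colnames(expr))
  if (!is.null(batch)) labels[names(batch)] <- batch
  if (anyNA(labels)) abort("unknown batch label for some samples",
                           "radresp_validation_error")
  if (!all(labels %in% model$batches)) {
    abort("batch label not present in correction model", "radresp_validation_error")
  }
  seen <- colnames(expr) %in% model$samples
  ref <- matrix(model$grand_mean[gi], nrow(expr), ncol(expr))
  if (any(seen)) {
    ref[, seen] <- model$stand_mean[gi, match(colnames(expr)[seen], model$samples)]
  }
  s <- (expr - ref) / sqrt(model$var_pooled[gi])
  out <- s
  for (b in unique(labels)) {
    cols <- which(labels == b)
    out[, cols] <- (s[, cols, drop = FALSE] - model$gamma_star[b, gi]) /
      sqrt(model$delta_star[b, gi])
  }
  out * sqrt(model$var_pooled[gi]) + ref
}

#' Invert a batch correction on corrected training data
#'
#' Exact inverse of [apply_combat()] for samples whose batch and
#' reference means are known, so `invert_combat(m, apply_combat(m, x))`
#' recovers `x` to numerical precision.
#'
#' @inheritParams apply_combat
#' @param corrected Corrected matrix.
#' @return The uncorrected matrix.
#' @export
invert_combat <- function(model, corrected, batch = NULL) {
  stopifnot(inherits(model, "combat_model"))
  if (model$single_batch) return(corrected)
  g <- rownames(corrected)
  gi <- match(g, model$genes)
  labels <- setNames(model$sample_batch[colnames(corrected)],
                     colnames(corrected))
  if (!is.null(batch)) labels[names(batch)] <- batch
  if (anyNA(labels)) abort("unknown batch label", "radresp_validation_error")
  seen <- colnames(corrected) %in% model$samples
  ref <- matrix(model$grand_mean[gi], nrow(corrected), ncol(corrected))
  if (any(seen)) {
    ref[, seen] <- model$stand_mean[gi, match(colnames(corrected)[seen], model$samples)]
  }
  s <- (corrected - ref) / sqrt(model$var_pooled[gi])
  out <- s
  for (b in unique(labels)) {
    cols <- which(labels == b)
    out[, cols] <- s[, cols, drop = FALSE] * sqrt(model$delta_star[b, gi]) +
      model$gamma_star[b, gi]
  }
  out * sqrt(model$var_pooled[gi]) + ref
}
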