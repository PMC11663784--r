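#' Configuration for the synthetic study generator
#'
#' The defaults emulate the structure of a two-cohort discovery set plus
#' one external validation cohort profiled on a different platform:
#' cohort sizes 125/124/107 with pCR prevalences 0.26/0.19/0.21, two
#' opposing planted signal blocks (an immune-like block higher in
#' responders, a stromal/TGF-beta-like block higher in non-responders),
#' per-cohort batch location/scale effects (larger for the validation
#' cohort), mild ordinal T/N-stage association with outcome, and
#' independent platform noise on the validation cohort that a pure
#' location/scale correction cannot model.
#'
#' @param n_genes Number of genes.
#' @param cohort_sizes Named integer vector; the last name in
#'   `validation_cohort` is treated as the external set.
#' @param pcr_prevalence Named vector of target outcome prevalences.
#' @param n_signal_up,n_signal_down Planted genes per block (responder-up
#'   and responder-down).
#' @param effect_size_sd_units Planted per-gene two-class standardised
#'   mean difference.
#' @param block_correlation Within-class pairwise correlation of genes in
#'   a signal block (shared latent factor).
#' @param batch_location_sd SD of per-gene additive batch shifts (log2
#'   units).
#' @param batch_scale_sd sdlog of per-gene multiplicative batch scale
#'   factors.
#' @param validation_batch_factor Multiplier on both batch SDs for the
#'   validation cohort (cross-platform shifts are larger).
#' @param validation_platform_noise_sd Independent technical noise on the
#'   validation cohort, in units of per-gene biological SD.
#' @param stage_outcome_log_or Log odds ratio per stage unit linking T/N
#'   stage to outcome.
#' @param baseline_mean_mu,baseline_mean_sd Hyperprior for per-gene
#'   baseline means (log2 microarray range).
#' @param baseline_sd_meanlog,baseline_sd_sdlog Lognormal hyperprior for
#'   per-gene biological SDs.
#' @param validation_cohort Name of the validation cohort.
#' @param seed Integer master seed; all draws derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_genes = 2000,
    cohort_sizes = c(grampian = 125, aristotle = 124, validation = 107),
    pcr_prevalence = c(grampian = 0.26, aristotle = 0.19, validation = 0.21),
    n_signal_up = 40, n_signal_down = 40,
    effect_size_sd_units = 1.0,
    block_correlation = 0.3,
    batch_location_sd = 0.3,
    batch_scale_sd = 0.1,
    validation_batch_factor = 2.5,
    validation_platform_noise_sd = 1.0,
    stage_outcome_log_or = 0.3,
    baseline_mean_mu = 7, baseline_mean_sd = 1.5,
    baseline_sd_meanlog = log(0.7), baseline_sd_sdlog = 0.3,
    validation_cohort = "validation",
    seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_signal_up + cfg$n_signal_down > cfg$n_genes) {
    abort("more planted genes than genes", "radresp_config_error")
  }
  if (!identical(sort(names(cfg$cohort_sizes)), sort(names(cfg$pcr_prevalence)))) {
    abort("cohort_sizes and pcr_prevalence must share names", "radresp_config_error")
  }
  if (any(cfg$pcr_prevalence <= 0 | cfg$pcr_prevalence >= 1)) {
    abort("prevalences must lie in (0,1)", "radresp_config_error")
  }
  bad <- round(cfg$cohort_sizes * cfg$pcr_prevalence)
  if (any(bad == 0 | bad == cfg$cohort_sizes)) {
    abort("degenerate config: expected event count rounds to 0 or n",
          "radresp_config_error")
  }
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    abort("block_correlation must be in [0,1)", "radresp_config_error")
  }
  structure(cfg, class = "simulation_config")
}

# Gene-level biology shared by every cohort: baseline moments and the
# planted-block bookkeeping. Deterministic in cfg$seed.
study_truth <- function(cfg) {
  local_seed(derive_seed(cfg$seed, "genes"), {
    genes <- sprintf("g%05d", seq_len(cfg$n_genes))
    m <- stats::rnorm(cfg$n_genes, cfg$baseline_mean_mu, cfg$baseline_mean_sd)
    s <- stats::rlnorm(cfg$n_genes, cfg$baseline_sd_meanlog, cfg$baseline_sd_sdlog)
    planted_idx <- sample.int(cfg$n_genes, cfg$n_signal_up + cfg$n_signal_down)
    up <- planted_idx[seq_len(cfg$n_signal_up)]
    down <- setdiff(planted_idx, up)
    planted <- data.frame(
      gene = genes[planted_idx],
      block = rep(c("up", "down"), c(cfg$n_signal_up, cfg$n_signal_down)),
      sign = rep(c(1, -1), c(cfg$n_signal_up, cfg$n_signal_down)),
      effect = cfg$effect_size_sd_units,
      stringsAsFactors = FALSE)
    list(genes = genes, gene_means = setNames(m, genes),
         gene_sds = setNames(s, genes), planted = planted,
         up_genes = genes[up], down_genes = genes[down], seed = cfg$seed)
  })
}

# Intercept making mean plogis(a0 + lp) equal the target prevalence for
# the realised stage linear predictors.
calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 lower = -20, upper = 20)$root
}

#' Simulate one cohort
#'
#' Baseline expression is Normal(per-gene mean, per-gene SD) on log2
#' scale. Planted genes carry a two-class mean shift of
#' `effect_size_sd_units` biological SDs (responder-up block positive,
#' responder-down block negative) plus a block-shared latent factor giving
#' within-class pairwise correlation `block_correlation`. Outcome is drawn
#' from a logistic model on T/N stage with an intercept calibrated to the
#' cohort's target prevalence. Per-gene batch location/scale effects and
#' (for the validation cohort) independent platform noise are applied on
#' top.
#'
#' @param cfg A [simulation_config()].
#' @param cohort_name One of `names(cfg$cohort_sizes)`.
#' @param truth Shared gene-level truth from a previous call (internal);
#'   regenerated from `cfg` when `NULL`.
#' @return List with `expr` (genes x samples), `samples` (sample table)
#'   and `truth` (planted structure, batch parameters, per-sample
#'   generating latent scores, seed).
#' @export
simulate_cohort <- function(cfg, cohort_name, truth = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!cohort_name %in% names(cfg$cohort_sizes)) {
    abort(paste0("unknown cohort: ", cohort_name), "radresp_config_error")
  }
  if (is.null(truth)) truth <- study_truth(cfg)
  n <- cfg$cohort_sizes[[cohort_name]]
  target <- cfg$pcr_prevalence[[cohort_name]]
  is_val <- identical(cohort_name, cfg$validation_cohort)
  bf <- if (is_val) cfg$validation_batch_factor else 1
  tau <- if (is_val) cfg$validation_platform_noise_sd else 0

  local_seed(derive_seed(cfg$seed, paste0("cohort_", cohort_name)), {
    ids <- sprintf("%s_s%03d", cohort_name, seq_len(n))
    t_stage <- sample(1:4, n, replace = TRUE, prob = c(0.05, 0.15, 0.60, 0.20))
    n_stage <- sample(0:2, n, replace = TRUE, prob = c(0.30, 0.45, 0.25))
    lp <- -cfg$stage_outcome_log_or * ((t_stage - 3) + (n_stage - 1))
    a0 <- calibrate_intercept(lp, target)
    pcr <- stats::rbinom(n, 1, stats::plogis(a0 + lp))

    G <- cfg$n_genes
    rho <- cfg$block_correlation
    e <- cfg$effect_size_sd_units
    z_up <- stats::rnorm(n); z_dn <- stats::rnorm(n)
    shift <- e * (pcr - target)

    bio <- matrix(stats::rnorm(G * n), G, n)
    up_i <- match(truth$up_genes, truth$genes)
    dn_i <- match(truth$down_genes, truth$genes)
    if (length(up_i)) {
      bio[up_i, ] <- sqrt(1 - rho) * bio[up_i, , drop = FALSE] +
        rep(sqrt(rho) * z_up + shift, each = length(up_i))
    }
    if (length(dn_i)) {
      bio[dn_i, ] <- sqrt(1 - rho) * bio[dn_i, , drop = FALSE] +
        rep(sqrt(rho) * z_dn - shift, each = length(dn_i))
    }
    s <- truth$gene_sds; m <- truth$gene_means
    bio <- bio * s + m  # recycle by row: s, m are length-G vectors

    batch_loc <- stats::rnorm(G, 0, cfg$batch_location_sd * bf)
    batch_scale <- exp(stats::rnorm(G, 0, cfg$batch_scale_sd * bf))
    expr <- m + batch_loc + batch_scale * (bio - m)
    if (tau > 0) {
      expr <- expr + (tau * s) * matrix(stats::rnorm(G * n), G, n)
    }
    dimnames(expr) <- list(truth$genes, ids)

    samples <- sample_table(data.frame(
      sample_id = ids, cohort = cohort_name, batch = cohort_name,
      pcr = pcr, t_stage = t_stage, n_stage = n_stage,
      stringsAsFactors = FALSE))
    # Infinite-gene limit of (up-block mean - down-block mean) on the
    # standardised scale: the generating discriminant used as the oracle.
    latent <- 2 * shift + sqrt(rho) * (z_up - z_dn)
    cohort_truth <- c(truth, list(
      cohort = cohort_name,
      batch_location = setNames(batch_loc, truth$genes),
      batch_scale = setNames(batch_scale, truth$genes),
      platform_noise_sd = tau,
      latent_score = setNames(latent, ids),
      intercept = a0))
    list(expr = expression_matrix(expr), samples = samples,
         truth = cohort_truth)
  })
}

#' Simulate the full study
#'
#' All cohorts share the same gene-level biology and planted blocks but
#' draw their own samples, outcomes and batch effects; the validation
#' cohort receives larger batch shifts plus platform noise so that batch
#' correction is non-trivial.
#'
#' @param cfg A [simulation_config()].
#' @return List with one entry per cohort (each as in [simulate_cohort()])
#'   plus `truth` (shared gene-level truth) and `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  truth <- study_truth(cfg)
  cohorts <- lapply(names(cfg$cohort_sizes), function(nm) {
    simulate_cohort(cfg, nm, truth = truth)
  })
  names(cohorts) <- names(cfg$cohort_sizes)
  log_stage("simulate_study", seed = cfg$seed,
            sizes = paste(cfg$cohort_sizes, collapse = "/"))
  list(cohorts = cohorts, truth = truth, config = cfg)
}

#' Bind cohorts into one matrix and sample table
#'
#' @param study Output of [simulate_study()].
#' @param which Cohort names to combine (default all).
#' @return List with `expr` and `samples`.
#' @export
combine_cohorts <- function(study, which = names(study$cohorts)) {
  exprs <- lapply(study$cohorts[which], `[[`, "expr")
  samples <- do.call(rbind, lapply(study$cohorts[which], `[[`, "samples"))
  list(expr = do.call(cbind, exprs), samples = sample_table(samples))
}
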