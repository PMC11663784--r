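# Shared small-data factories for the test suite.

# Minimal valid sample table with a fixed outcome pattern.
make_samples <- function(n, n_pos, cohort = "c", batch = cohort,
                         prefix = cohort) {
  ids <- sprintf("%s_s%03d", prefix, seq_len(n))
  sample_table(data.frame(
    sample_id = ids, cohort = cohort, batch = batch,
    pcr = rep(c(1L, 0L), c(n_pos, n - n_pos)),
    t_stage = rep_len(c(2L, 3L, 3L, 4L), n),
    n_stage = rep_len(c(0L, 1L, 2L), n),
    stringsAsFactors = FALSE))
}

# Gaussian expression matrix with optional per-class mean shift on
# selected genes (shift applied to class-1 columns).
make_expr <- function(n_genes, samples, shift_genes = character(0),
                      shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * nrow(samples), mean = 7, sd = sd),
              n_genes, nrow(samples),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              samples$sample_id))
  if (length(shift_genes)) {
    pos <- samples$sample_id[samples$pcr == 1]
    x[shift_genes, pos] <- x[shift_genes, pos] + shift
  }
  x
}

# Small two-cohort-plus-validation synthetic config for pipeline tests.
small_config <- function(seed = 1, effect = 1.5, n_genes = 400) {
  simulation_config(
    n_genes = n_genes,
    cohort_sizes = c(d1 = 60, d2 = 60, val = 60),
    pcr_prevalence = c(d1 = 0.26, d2 = 0.19, val = 0.21),
    n_signal_up = 15, n_signal_down = 15,
    effect_size_sd_units = effect,
    validation_cohort = "val", seed = seed)
}
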