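#' Validate a sample annotation table
#'
#' Mandatory columns: `sample_id`, `cohort`, `batch`, `pcr` (binary 0/1 or
#' `NA` for prediction-only inputs), `t_stage` (1-4 or `NA`), `n_stage`
#' (0-2 or `NA`). Optional ordinal columns `response_grade` and `yt_stage`
#' carry graded-response and post-treatment stage checks.
#'
#' @param tab A data.frame.
#' @param require_pcr Disallow missing outcome (modelling inputs).
#' @return The validated data.frame.
#' @export
sample_table <- function(tab, require_pcr = FALSE) {
  need <- c("sample_id", "cohort", "batch", "pcr", "t_stage", "n_stage")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("sample table missing columns: ", paste(miss, collapse = ", ")),
          "radresp_format_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    abort("duplicate sample_id in sample table", "radresp_validation_error")
  }
  if (!all(tab$pcr %in% c(0, 1, NA))) {
    abort("pcr must be 0, 1 or NA", "radresp_validation_error")
  }
  if (require_pcr && anyNA(tab$pcr)) {
    abort("missing pcr not allowed for modelling inputs", "radresp_validation_error")
  }
  if (!all(is.na(tab$t_stage) | tab$t_stage %in% 1:4)) {
    abort("t_stage must be in 1..4 or NA", "radresp_validation_error")
  }
  if (!all(is.na(tab$n_stage) | tab$n_stage %in% 0:2)) {
    abort("n_stage must be in 0..2 or NA", "radresp_validation_error")
  }
  tab
}

#' Read / write sample annotation TSVs
#' @param path TSV with the mandatory columns of [sample_table()].
#' @param ... Passed to [sample_table()].
#' @return Validated data.frame.
#' @export
read_sample_table <- function(path, ...) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  sample_table(tab, ...)
}

#' @rdname read_sample_table
#' @param tab Sample table.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge cohort annotation tables into one discovery table
#'
#' Pure bookkeeping used when several cohorts are pooled into a single
#' discovery set: concatenates rows, checks id uniqueness, and reports the
#' pooled outcome prevalence.
#'
#' @param tables List of sample tables.
#' @return List with `table` (merged data.frame), `n`, `n_pcr`, and
#'   `prevalence` (= n_pcr / n over samples with non-missing outcome).
#' @export
merge_cohorts <- function(tables) {
  stopifnot(length(tables) >= 1L)
  tables <- lapply(tables, sample_table)
  merged <- do.call(rbind, tables)
  if (anyDuplicated(merged$sample_id)) {
    abort("sample_id collision across merged cohorts", "radresp_validation_error")
  }
  ok <- !is.na(merged$pcr)
  list(table = merged, n = sum(ok), n_pcr = sum(merged$pcr[ok]),
       prevalence = sum(merged$pcr[ok]) / sum(ok))
}

#' Read a copy-number segment table
#'
#' SEG-like TSV with columns `sample_id`, `chrom`, `start`, `end`, `call`
#' (`loss` / `neutral` / `gain`); coordinates 1-based inclusive. Segments
#' of one sample on one chromosome must not overlap.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_segments <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  validate_segments(tab)
}

#' @rdname read_segments
#' @param tab Segment data.frame.
#' @export
validate_segments <- function(tab) {
  need <- c("sample_id", "chrom", "start", "end", "call")
  if (!all(need %in% names(tab))) {
    abort("segment table needs sample_id, chrom, start, end, call",
          "radresp_format_error")
  }
  if (!all(tab$call %in% c("loss", "neutral", "gain"))) {
    abort("segment call must be loss/neutral/gain", "radresp_validation_error")
  }
  if (any(tab$end < tab$start)) {
    abort("segment end < start", "radresp_validation_error")
  }
  by_sc <- split(tab, list(tab$sample_id, tab$chrom), drop = TRUE)
  for (d in by_sc) {
    if (nrow(d) < 2L) next
    d <- d[order(d$start), ]
    if (any(d$start[-1] <= d$end[-nrow(d)])) {
      abort(sprintf("overlapping segments for sample %s chrom %s",
                    d$sample_id[1], d$chrom[1]), "radresp_validation_error")
    }
  }
  tab
}
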