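#' Construct and validate an expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix of
#' log2-scale values with genes in rows and samples in columns, carrying
#' unique, non-empty dimnames. All pipeline stages consume and return this
#' shape; keeping a single canonical orientation avoids silent
#' transposition bugs.
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `values`.
#' @param allow_missing Permit `NA` cells (only raw, pre-QC matrices may
#'   contain them; see [quality_check()]).
#' @param assume_log2 When `TRUE` (default) values are taken to be on log2
#'   scale; a heuristic warning is emitted when the maximum exceeds 30
#'   (likely unlogged data). No transformation is ever applied silently.
#' @return The validated matrix (invisibly classed as used elsewhere).
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              allow_missing = FALSE, assume_log2 = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("expression values must be a numeric matrix", "radresp_format_error")
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  gn <- rownames(values); sn <- colnames(values)
  if (is.null(gn) || is.null(sn)) {
    abort("expression matrix needs gene rownames and sample colnames",
          "radresp_validation_error")
  }
  if (anyDuplicated(gn)) {
    abort("duplicate gene ids in expression matrix", "radresp_validation_error")
  }
  if (anyDuplicated(sn)) {
    abort("duplicate sample ids in expression matrix", "radresp_validation_error")
  }
  if (!allow_missing && anyNA(values)) {
    abort("expression matrix contains missing values; run quality_check() first",
          "radresp_validation_error")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort("expression matrix contains non-finite values", "radresp_validation_error")
  }
  if (assume_log2 && max(values, na.rm = TRUE) > 30) {
    warn_log("maximum expression value exceeds 30; data may not be log2 scale")
  }
  values
}

#' Read an expression matrix from disk
#'
#' TSV dialect: genes in rows, first column gene ids, header row of sample
#' ids, tab separated. MTX dialect: MatrixMarket file accompanied by
#' `<path>.genes` and `<path>.samples` index files (one id per line).
#' Duplicate gene rows (several probesets mapping to one gene) are
#' collapsed by keeping the row with the highest mean expression, the
#' standard deterministic rule.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @param collapse Duplicate-gene rule; only `"max_mean"` is implemented.
#' @param allow_missing Passed to [expression_matrix()].
#' @return Validated genes x samples numeric matrix.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            collapse = "max_mean", allow_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path), "radresp_io_error")
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L) {
      abort("malformed expression header: need gene column plus >=1 sample",
            "radresp_format_error")
    }
    sample_ids <- header[-1]
    if (anyDuplicated(sample_ids)) {
      abort("duplicate sample id in expression header", "radresp_validation_error")
    }
    tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             check.names = FALSE, colClasses = c("character",
                             rep("numeric", length(sample_ids))),
                             comment.char = "")
    vals <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(!is.na(vals) & !is.finite(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf("non-finite expression value at row %d, column %d",
                    bad[1, 1], bad[1, 2]), "radresp_parse_error")
    }
    rownames(vals) <- tab[[1]]
    colnames(vals) <- sample_ids
  } else {
    m <- Matrix::readMM(path)
    gene_ids <- readLines(paste0(path, ".genes"))
    sample_ids <- readLines(paste0(path, ".samples"))
    if (nrow(m) != length(gene_ids) || ncol(m) != length(sample_ids)) {
      abort("MTX dimensions disagree with index files", "radresp_format_error")
    }
    vals <- as.matrix(m)
    dimnames(vals) <- list(gene_ids, sample_ids)
  }
  vals <- collapse_duplicate_genes(vals, rule = collapse)
  expression_matrix(vals, allow_missing = allow_missing)
}

# Keep, per duplicated gene id, the row with the highest mean expression.
collapse_duplicate_genes <- function(vals, rule = "max_mean") {
  stopifnot(identical(rule, "max_mean"))
  gn <- rownames(vals)
  if (!anyDuplicated(gn)) return(vals)
  means <- rowMeans(vals, na.rm = TRUE)
  ord <- order(gn, -means)
  keep <- ord[!duplicated(gn[ord])]
  keep <- sort(keep)  # preserve original row order of the retained rows
  warn_log(sprintf("collapsed %d duplicate gene rows by max mean",
                   nrow(vals) - length(keep)))
  vals[keep, , drop = FALSE]
}

#' Write an expression matrix
#'
#' @inheritParams read_expression
#' @param expr Genes x samples matrix.
#' @export
write_expression <- function(expr, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(expr), "generalMatrix"),
                                "CsparseMatrix"), path)
    writeLines(rownames(expr), paste0(path, ".genes"))
    writeLines(colnames(expr), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member...`. Duplicate members
#' within a set are removed with a warning; an empty file yields an empty
#' collection.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), "radresp_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i),
            "radresp_format_error")
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn_log(sprintf("GMT set '%s': %d duplicate members removed",
                       f[1], sum(duplicated(members))))
      members <- unique(members)
    }
    if (f[1] %in% names(sets)) {
      abort(sprintf("duplicate GMT set name '%s'", f[1]), "radresp_validation_error")
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Define a scoring signature
#'
#' @param name Signature name.
#' @param genes Unique, non-empty gene id vector.
#' @param weights Optional per-gene weights (default 1), aligned to `genes`.
#' @param direction `+1` or `-1`; `-1` negates the score.
#' @return A `signature_def` object.
#' @export
signature_def <- function(name, genes, weights = NULL, direction = 1) {
  if (length(genes) == 0L) abort("signature has no genes", "radresp_validation_error")
  if (anyDuplicated(genes)) abort("signature genes must be unique", "radresp_validation_error")
  if (is.null(weights)) weights <- rep(1, length(genes))
  if (length(weights) != length(genes)) {
    abort("weights must align 1:1 with genes", "radresp_validation_error")
  }
  if (!direction %in% c(-1, 1)) abort("direction must be +1 or -1", "radresp_validation_error")
  structure(list(name = name, genes = as.character(genes),
                 weights = as.numeric(weights), direction = direction),
            class = "signature_def")
}

#' Read weighted signature definitions from a TSV
#'
#' Expected columns: `name`, `gene`, optional `weight`, optional
#' `direction` (constant within a signature).
#' @param path TSV path.
#' @return List of [signature_def()] objects.
#' @export
read_signatures <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "gene") %in% names(tab))) {
    abort("signature TSV needs 'name' and 'gene' columns", "radresp_format_error")
  }
  lapply(split(tab, tab$name), function(d) {
    signature_def(d$name[1], d$gene,
                  weights = if ("weight" %in% names(d)) d$weight else NULL,
                  direction = if ("direction" %in% names(d)) d$direction[1] else 1)
  })
}
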