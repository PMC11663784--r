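#' Score a gene signature per sample
#'
#' `mean_z` (default for unweighted candidate sets) is the mean, over
#' signature genes present in the matrix, of per-gene z-scores computed
#' across the scored cohort; it is scale-free and has cohort mean zero
#' when all genes are present. `weighted_sum` is the plain weighted sum of
#' expression, the convention for published signatures that ship fixed
#' coefficients (e.g. radiosensitivity indices supplied as
#' [signature_def()] weights). `direction = -1` negates the score.
#' Zero-variance genes are excluded with a warning under `mean_z`.
#'
#' @param expr Genes x samples matrix.
#' @param sig A [signature_def()].
#' @param method `"mean_z"` or `"weighted_sum"`.
#' @param reference_moments Optional list with `mean` and `sd` named
#'   vectors freezing the z-scoring moments (e.g. from a discovery
#'   cohort); default is within-cohort moments.
#' @return Named numeric vector, one score per sample.
#' @export
score_signature <- function(expr, sig, method = c("mean_z", "weighted_sum"),
                            reference_moments = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(sig, "signature_def"))
  present <- sig$genes %in% rownames(expr)
  if (!any(present)) {
    abort(paste0("no gene of signature '", sig$name, "' present"),
          "radresp_scoring_error")
  }
  genes <- sig$genes[present]
  w <- sig$weights[present]
  x <- expr[genes, , drop = FALSE]
  if (method == "mean_z") {
    if (is.null(reference_moments)) {
      mu <- rowMeans(x); sdv <- sqrt(row_vars(x))
    } else {
      mu <- reference_moments$mean[genes]; sdv <- reference_moments$sd[genes]
    }
    keep <- is.finite(sdv) & sdv > 0
    if (!all(keep)) {
      warn_log(sprintf("signature '%s': %d zero-variance genes excluded",
                       sig$name, sum(!keep)))
      if (!any(keep)) {
        abort(paste0("signature '", sig$name, "' has only zero-variance genes"),
              "radresp_scoring_error")
      }
      x <- x[keep, , drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
    }
    score <- colMeans((x - mu) / sdv)
  } else {
    score <- colSums(x * w)
  }
  sig$direction * setNames(as.numeric(score), colnames(expr))
}

#' Marker-mean cell-population scores
#'
#' Per population, the score is the arithmetic mean of member-gene log2
#' expression (the marker-mean estimator used by MCP-counter-style
#' methods); no cross-sample normalisation is applied, so scores are
#' comparable across samples within a matrix. A population with no marker
#' present yields a column of `NA` with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param marker_sets Named list of marker gene vectors (GMT semantics).
#' @return Samples x populations numeric matrix.
#' @export
score_cell_populations <- function(expr, marker_sets) {
  out <- sapply(names(marker_sets), function(nm) {
    genes <- intersect(marker_sets[[nm]], rownames(expr))
    if (!length(genes)) {
      warn_log(paste0("no marker of population '", nm, "' present"))
      return(rep(NA_real_, ncol(expr)))
    }
    colMeans(expr[genes, , drop = FALSE])
  })
  rownames(out) <- colnames(expr)
  out
}

#' Nearest-centroid model
#'
#' @param centroids Genes x classes numeric matrix of per-class centroid
#'   expression.
#' @param threshold Minimum Pearson correlation for a confident call;
#'   below it a sample is `"unclassified"`.
#' @param min_gene_fraction Minimum fraction of centroid genes that must
#'   be present in a scored matrix.
#' @return A `centroid_model`.
#' @export
centroid_model <- function(centroids, threshold = 0.15,
                           min_gene_fraction = 0.5) {
  stopifnot(is.matrix(centroids), !is.null(rownames(centroids)),
            !is.null(colnames(centroids)))
  if (threshold < -1 || threshold > 1) {
    abort("threshold must be in [-1,1]", "radresp_validation_error")
  }
  structure(list(centroids = centroids, threshold = threshold,
                 min_gene_fraction = min_gene_fraction),
            class = "centroid_model")
}

#' Nearest-centroid subtype calls
#'
#' Each sample is assigned the class whose centroid has the highest
#' Pearson correlation with the sample's expression over the shared gene
#' list; a maximum below the model threshold yields `"unclassified"`.
#' Ties are broken by centroid column order (logged). Because Pearson
#' correlation is invariant to per-sample affine transforms, the calls
#' are too.
#'
#' @param expr Genes x samples matrix.
#' @param model A [centroid_model()].
#' @return data.frame with `sample_id`, `call`, `correlation`.
#' @export
classify_subtype <- function(expr, model) {
  stopifnot(inherits(model, "centroid_model"))
  genes <- intersect(rownames(model$centroids), rownames(expr))
  if (length(genes) < model$min_gene_fraction * nrow(model$centroids)) {
    abort(sprintf("only %d/%d centroid genes present (< %.0f%%)",
                  length(genes), nrow(model$centroids),
                  100 * model$min_gene_fraction), "radresp_classification_error")
  }
  cors <- stats::cor(expr[genes, , drop = FALSE],
                     model$centroids[genes, , drop = FALSE])
  classes <- colnames(model$centroids)
  best <- apply(cors, 1, which.max)  # first max wins on ties
  ties <- apply(cors, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) warn_log(sprintf("%d tied centroid calls broken by class order",
                                  sum(ties)))
  maxcor <- cors[cbind(seq_len(nrow(cors)), best)]
  call <- ifelse(maxcor < model$threshold, "unclassified", classes[best])
  data.frame(sample_id = colnames(expr), call = call, correlation = maxcor,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chromosomal-instability flag from copy-number segments
#'
#' A sample whose neutral segments cover more than 20% of the combined
#' length of all its segments is classified CIN-negative, otherwise
#' CIN-positive (strict `>`; a neutral fraction of exactly the threshold
#' is CIN-positive). Segment lengths are `end - start + 1` (1-based
#' inclusive), so the flag is invariant to splitting a segment into
#' contiguous halves. Samples without segments get `NA` with a warning.
#'
#' @param segments Segment table (see [read_segments()]).
#' @param neutral_threshold Neutral-fraction cut, default 0.20.
#' @return Named integer vector: 1 = CIN-positive, 0 = CIN-negative.
#' @export
classify_cin <- function(segments, neutral_threshold = 0.20) {
  segments <- validate_segments(segments)
  lens <- segments$end - segments$start + 1
  tot <- tapply(lens, segments$sample_id, sum)
  neu <- tapply(lens * (segments$call == "neutral"), segments$sample_id, sum)
  frac <- neu / tot
  flag <- as.integer(!(frac > neutral_threshold))
  setNames(flag, names(tot))
}

#' Per-sample mutation burden
#'
#' Counts records per sample, optionally restricted to a set of mutation
#' classes (default: nonsynonymous classes). Samples listed in
#' `sample_ids` but absent from the table get 0 with a warning.
#'
#' @param mutations data.frame with `sample_id`, `gene`, `class`.
#' @param classes Classes to count; `NULL` counts everything.
#' @param sample_ids Optional universe of samples for the output.
#' @return Named integer vector of counts.
#' @export
mutation_burden <- function(mutations,
                            classes = c("missense", "nonsense", "frameshift",
                                        "splice_site"),
                            sample_ids = NULL) {
  if (nrow(mutations) && !is.null(classes)) {
    mutations <- mutations[mutations$class %in% classes, , drop = FALSE]
  }
  counts <- table(mutations$sample_id)
  ids <- sample_ids %||% names(counts)
  out <- setNames(as.integer(counts[ids]), ids)
  if (anyNA(out)) {
    warn_log(sprintf("%d samples absent from mutation table; burden set to 0",
                     sum(is.na(out))))
    out[is.na(out)] <- 0L
  }
  out
}
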