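#' Locked classifier objects
#'
#' A locked model freezes everything needed to reproduce its predictions:
#' the algorithm, the gene list, hyperparameters, the fitted payload and
#' the training seed. External validation may *apply* a locked model but
#' never refit it; [model_hash()] gives the identity used to assert that.
#'
#' @param algorithm_id One of the registry algorithms (e.g.
#'   `"boosted_trees"`).
#' @param gene_list Unique, non-empty character vector of predictor genes.
#' @param hyperparameters Named list.
#' @param payload Fitted-parameter payload from the learner registry.
#' @param training_seed Integer seed the fit was performed under.
#' @param cv_accuracy Cross-validation accuracy recorded at selection time.
#' @param created_from Free-text provenance string.
#' @return A `locked_model`.
#' @export
locked_model <- function(algorithm_id, gene_list, hyperparameters, payload,
                         training_seed, cv_accuracy = NA_real_,
                         created_from = "") {
  if (length(gene_list) == 0L || anyDuplicated(gene_list)) {
    abort("gene_list must be non-empty and unique", "radresp_validation_error")
  }
  # canonical numeric storage so a JSON round-trip (which may parse whole
  # numbers back as integers) preserves the model hash
  hyperparameters <- lapply(hyperparameters, function(v) {
    if (is.integer(v)) as.numeric(v) else v
  })
  structure(list(algorithm_id = algorithm_id,
                 gene_list = as.character(gene_list),
                 hyperparameters = hyperparameters,
                 payload = payload,
                 training_seed = as.integer(training_seed),
                 cv_accuracy = cv_accuracy,
                 created_from = created_from),
            class = "locked_model")
}

#' Score samples with a locked model
#'
#' @param object A `locked_model`.
#' @param expr Genes x samples expression matrix containing every model
#'   gene.
#' @param ... Unused.
#' @return Numeric vector of P(pCR) per sample, named by sample id.
#' @export
predict.locked_model <- function(object, expr, ...) {
  missing <- setdiff(object$gene_list, rownames(expr))
  if (length(missing)) {
    abort(paste0("model genes absent from expression matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          "radresp_validation_error")
  }
  x <- t(expr[object$gene_list, , drop = FALSE])
  p <- learner_predict(object$algorithm_id, object$payload, x)
  setNames(p, colnames(expr))
}

#' Identity hash of a locked model
#'
#' SHA-256 over the algorithm, gene list, hyperparameters, seed and the
#' serialized fitted payload; identical hash implies identical predictions.
#' @param model A `locked_model`.
#' @return Character scalar.
#' @export
model_hash <- function(model) {
  digest::digest(list(model$algorithm_id, model$gene_list,
                      model$hyperparameters, model$training_seed,
                      serialize_payload(model$payload)), algo = "sha256")
}

# External-pointer-backed fits (xgboost boosters) are replaced by their
# exported raw bytes before serialization, so the byte representation —
# and therefore the model hash and the saved file — does not depend on
# in-memory handle state and survives save/load round-trips unchanged.
canonical_payload <- function(payload) {
  lapply(payload, function(el) {
    if (inherits(el, "xgb.Booster")) {
      structure(list(bytes = xgboost::xgb.save.raw(el)),
                class = "radresp_xgb_raw")
    } else el
  })
}

restore_payload <- function(payload) {
  lapply(payload, function(el) {
    if (inherits(el, "radresp_xgb_raw")) xgboost::xgb.load.raw(el$bytes)
    else el
  })
}

serialize_payload <- function(payload) {
  serialize(canonical_payload(payload), connection = NULL, version = 2,
            xdr = TRUE)
}

MODEL_SCHEMA_VERSION <- 1L

#' Save / load a locked model
#'
#' The on-disk format is a JSON envelope
#' `{schema_version, algorithm_id, gene_list, hyperparameters, seed,
#' cv_accuracy, created_from, payload_base64, payload_sha256}`. The
#' payload hash is verified on load; a mismatch (tampered or truncated
#' file) raises an integrity error, and a file without a known
#' `schema_version` is refused explicitly.
#'
#' @param model A `locked_model`.
#' @param path File path.
#' @return `load_model` returns the restored `locked_model`, whose
#'   predictions are bitwise identical to the saved one.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "locked_model"))
  raw <- serialize_payload(model$payload)
  env <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    algorithm_id = model$algorithm_id,
    gene_list = model$gene_list,
    hyperparameters = model$hyperparameters,
    seed = model$training_seed,
    cv_accuracy = model$cv_accuracy,
    created_from = model$created_from,
    payload_base64 = base64enc::base64encode(raw),
    payload_sha256 = digest::digest(raw, algo = "sha256", serialize = FALSE)
  )
  writeLines(jsonlite::toJSON(env, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  env <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (is.null(env$schema_version) || env$schema_version != MODEL_SCHEMA_VERSION) {
    abort("unsupported or missing model schema version", "radresp_version_error")
  }
  raw <- base64enc::base64decode(env$payload_base64)
  if (!identical(digest::digest(raw, algo = "sha256", serialize = FALSE),
                 env$payload_sha256)) {
    abort("model payload hash mismatch: file corrupted or tampered",
          "radresp_integrity_error")
  }
  locked_model(env$algorithm_id, env$gene_list, as.list(env$hyperparameters),
               restore_payload(unserialize(raw)), env$seed,
               cv_accuracy = env$cv_accuracy %||% NA_real_,
               created_from = env$created_from %||% "")
}
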