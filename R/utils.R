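#' @keywords internal
"_PACKAGE"

# Seeded evaluation that never disturbs the caller's RNG stream.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, staying inside
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "radresp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_log <- function(...) warning(..., call. = FALSE)

# Structured progress line; silenced unless option radresp.verbose is TRUE.
log_stage <- function(stage, ...) {
  if (isTRUE(getOption("radresp.verbose", FALSE))) {
    info <- paste(vapply(list(...), function(x) paste(x, collapse = ","),
                         character(1)), collapse = " ")
    message(sprintf("[radresp] %s %s", stage, info))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}
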