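#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib trcensus, .registration = TRUE
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed and a stage tag
#'
#' Every source of randomness in the package draws from a child seed derived
#' from the single user-facing seed, so individual stages can be rerun in
#' isolation while the end-to-end run stays deterministic.  The derived value
#' always fits in a 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param tag character stage tag.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 69621 + h * 1013) %% 2147483587L + 1L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

# leaf names must survive a Newick round trip without quoting
sanitize_label <- function(x) gsub("[();:, ]", "_", x)
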