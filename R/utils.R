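#' @keywords internal
#' @useDynLib soluq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' @importFrom stats rnorm runif sd cor quantile coef predict residuals simulate fitted
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All reproducibility in the package flows
# through this helper so that library calls never clobber user RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit signed integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 9973 * as.numeric(index)) %% 2147483587)
}

soluq_log <- function(..., verbose = getOption("soluq.verbose", TRUE)) {
  if (isTRUE(verbose)) message("soluq: ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
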