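#' @useDynLib cardiofuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov TukeyHSD fft rbeta runif rnorm sd quantile
#' @importFrom utils write.csv read.csv head
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generator determinism contracts rest on this helper.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

match_one <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices)
    stopf("invalid %s: '%s' (expected one of %s)", what,
          paste(x, collapse = ","), paste(choices, collapse = ", "))
  x
}
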