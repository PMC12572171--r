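#' @useDynLib iacdfc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois sd cor pnorm pt p.adjust median complete.cases
#' @importFrom utils head combn write.table read.table packageVersion
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Population (n-denominator) z-score of a vector; errors on zero variance.
zscore_pop <- function(x, label = "series") {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("zero-variance ", label, ": cannot standardize", call. = FALSE)
  (x - m) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}
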