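## Internal helpers shared across modules.

#' @useDynLib pgscontext, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dnorm integrate lm lm.wfit median optim pnorm
#'   pt qnorm quantile rbinom rnorm runif sd setNames var predict
#' @importFrom utils read.delim write.table str packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config("`%s` must be a single integer >= %d (got %s)", name, min,
                paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_config("`%s` must be a number in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

## Seed handling: all stochastic entry points take a `seed` argument and run
## under a locally restored RNG state, so library calls never disturb the
## caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7907 * k) %% 2147483629
}

is_binary <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}
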