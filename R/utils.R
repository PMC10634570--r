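#' @importFrom stats cor quantile rnorm runif sd var median fft t.test
#'   pt cmdscale dist wilcox.test lm.fit setNames
#' @importFrom utils combn head read.csv write.csv
NULL

# Derive a reproducible child seed from a master seed and a stage offset.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + as.double(offset) * 12347) %% 2147483587)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
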