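#' @useDynLib tfspm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom tools md5sum
#' @importFrom stats rnorm runif qt pt sd median var mad optim fft mvfft nextn
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs under the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, keeping within 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(..., call. = FALSE)
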