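#' Derive a reproducible substream seed
#'
#' All randomness in the synthetic-culture generator flows from one integer
#' seed; per-neuron (and per-stage) substreams are derived with a small
#' multiplicative hash so that neurons are statistically independent yet the
#' whole culture is reproducible bit-for-bit from the master seed.
#'
#' @param seed master integer seed.
#' @param ... one or more non-negative integer keys identifying the substream
#'   (e.g. a stage code and a neuron index).
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that library code never
#' perturbs the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
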