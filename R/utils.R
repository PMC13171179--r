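#' @useDynLib morphograph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Derive a reproducible 32-bit sub-seed from a master seed and a stream id.
# Keeps every derived seed in [0, 2^31): R's set.seed() takes 32-bit integers.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
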