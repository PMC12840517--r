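# Internal helpers.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state so
# that seeded subroutines do not perturb surrounding randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a child seed from a base seed and a stage offset, kept within
# 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}
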