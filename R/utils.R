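## Run expr with a temporarily seeded RNG, restoring the caller's state.
## All generator/fitting randomness goes through this so that identical
## (config, seed) pairs are bit-identical and callers' RNG is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a stream-specific child seed, kept within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

stopNamed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "myofuseError")))
}

assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopNamed("myofuse_invalid_argument", "%s must be a positive scalar", name)
}
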