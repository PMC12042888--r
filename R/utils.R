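# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed (kept well inside 32-bit integer range).
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483477L)
}

.isWholeNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  abs(x - round(x)) < 1e-8
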