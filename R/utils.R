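# Internal helpers: seed derivation and scoped RNG.

# Derive a reproducible sub-seed from a top-level seed and a stage tag.
# Every stochastic stage draws from its own named substream so that adding
# or reordering stages never perturbs the others.  Result is kept well
# below 2^31 - 1.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(tag))
  v <- utf8ToInt(tag)
  h <- sum(v * (31^(seq_along(v) %% 7))) %% 2147483629
  as.integer((abs(as.double(seed)) %% 2146000000 * 10007 + h) %% 2147483629)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
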