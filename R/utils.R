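# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
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

# Deterministic child seed from a master seed and a key (integer vector or
# index). Kept below 2^31 - 1; path-independent so the same subproblem always
# draws the same stream.
derive_seed <- function(seed, key) {
  x <- as.double(seed) %% 2147483647
  for (v in as.double(key)) {
    x <- (x * 48271 + v + 1) %% 2147483647
  }
  as.integer(x)
}
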