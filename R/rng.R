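# Seed plumbing: every stochastic operation takes an explicit integer seed and
# runs inside a local RNG scope so callers' .Random.seed is never disturbed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream splitting; stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + as.numeric(i) * 7919) %%
               2147483647)
}
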