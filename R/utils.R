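# Small internal utilities.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  Keeps every stochastic operation in the
# package locally seeded and side-effect free.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a child seed from a base seed and a stream index, staying well below
# .Machine$integer.max.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(stream) %% 1000L)
}
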