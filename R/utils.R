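# RNG helpers: run code under a fixed seed without disturbing the caller's
# RNG state.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Deterministic stage-local seed derived from a master seed. Kept well below
# .Machine$integer.max.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 97 + as.numeric(stage) * 1009) %% 2000000011)
}
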