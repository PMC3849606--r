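# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive named sub-seeds from one master seed so that independent stages
# (network topology, initial states, noise, ...) consume independent streams.
stream_seeds <- function(seed, streams) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(streams))
    names(s) <- streams
    s
  })
}
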