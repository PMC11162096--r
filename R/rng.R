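# RNG substreams for reproducible simulation.
#
# Each trial derives two independent L'Ecuyer-CMRG substreams from its seed:
# one drives outcome generation (the scenario), the other posterior sampling.
# Keeping the streams separate means adding posterior draws never perturbs
# the simulated patients, and per-trial seeds make parallel and serial
# execution agree.

new_rng_stream <- function(seed, stream = 1L) {
  env <- new.env(parent = emptyenv())
  if (is.null(seed)) {
    env$state <- NULL  # ambient RNG passthrough
    return(env)
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(as.integer(seed) %% .Machine$integer.max,
                            kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", globalenv(), inherits = FALSE)
  for (i in seq_len(stream - 1L)) s <- parallel::nextRNGStream(s)
  env$state <- s
  env
}

# Evaluate `code` with the stream's RNG state installed; the advanced state
# is written back to the stream so successive calls continue the sequence.
with_stream <- function(stream, code) {
  if (is.null(stream$state)) return(code)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  code
}

# Order-independent per-trial seed derivation from a master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.double(seed) + 1000003 * seq_len(n)) %% 2147483647)
}
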