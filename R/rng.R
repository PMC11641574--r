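# Seeded RNG substreams.
#
# One master seed yields independent named substream seeds so that toggling
# one stochastic component (solvent initialisation, MPC shifts/axes,
# reactions, geometry sampling) does not perturb the draws of the others.
# Streams are carried through the run as saved .Random.seed vectors.

STREAM_NAMES <- c("geometry", "solvent", "mpc", "react")

derive_stream_seeds <- function(master) {
  with_seed(as.integer(master) %% .Machine$integer.max, {
    s <- sample.int(.Machine$integer.max - 1L, length(STREAM_NAMES))
    names(s) <- STREAM_NAMES
    s
  })
}

# evaluate expr under a given integer seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

make_streams <- function(master) {
  seeds <- derive_stream_seeds(master)
  lapply(seeds, function(s) with_seed(s, get(".Random.seed", globalenv())))
}

# run fn() with the named stream's RNG state active; returns list(value,
# streams) with the advanced stream state stored back
stream_run <- function(streams, name, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", streams[[name]], envir = globalenv())
  val <- fn()
  streams[[name]] <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  list(value = val, streams = streams)
}
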