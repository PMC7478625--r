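# Private seeded RNG streams: all simulator/bootstrap randomness flows
# from one integer seed through a stream object, without touching the
# caller's .Random.seed.

.seededRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

.withRNG <- function(rng, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

.rngSampleInt <- function(rng, n, size, replace = FALSE)
  .withRNG(rng, sample.int(n, size, replace = replace))

.rngSample <- function(rng, x, size = length(x), replace = FALSE,
                       prob = NULL)
  .withRNG(rng, sample(x, size, replace = replace, prob = prob))

.rngUnif <- function(rng, n, min = 0, max = 1)
  .withRNG(rng, stats::runif(n, min, max))

.rngExp <- function(rng, n, rate) .withRNG(rng, stats::rexp(n, rate))

.rngNorm <- function(rng, n, mean = 0, sd = 1)
  .withRNG(rng, stats::rnorm(n, mean, sd))

.rngPois <- function(rng, n, lambda) .withRNG(rng, stats::rpois(n, lambda))

.rngBinom <- function(rng, n, prob) .withRNG(rng, stats::runif(n) < prob)
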