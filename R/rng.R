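# Seeded private RNG streams.  Generators never touch the caller's global
# random state: each stream keeps its own .Random.seed and swaps it in only
# for the duration of a draw.

new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(as.integer(seed))
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  draw <- function(fn) {
    function(...) {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      fn(...)
    }
  }
  list(sample = draw(sample),
       runif = draw(stats::runif),
       rnorm = draw(stats::rnorm),
       rbinom = draw(stats::rbinom),
       sample_int = draw(sample.int),
       derive = function(offset) new_rng((as.integer(seed) + offset) %% .Machine$integer.max))
}

# Run expr with a temporary seed, restoring the caller's random state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}
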