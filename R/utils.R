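# Internal helpers: seeded evaluation and argument checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All exported stochastic functions route
# their randomness through this so that a single integer seed reproduces any
# result without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# Derive a stage-specific sub-seed from a master seed; keeps results of one
# stage invariant to how much randomness another stage consumed. Stays well
# below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  offsets <- c(
    tree = 11L, traits = 23L, sequences = 37L, metacommunity = 53L,
    assembly = 71L, classes = 89L, neutral = 101L, nti = 127L,
    pcg = 151L, pipeline = 173L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 2000000L) * 1000L + off
}

stop_pcg <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_pcg(what, " must be TRUE or FALSE")
  }
  invisible(x)
}

check_number <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_pcg(what, " must be a single number")
  }
  if (x < lower || x > upper) {
    stop_pcg(what, " must be in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
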