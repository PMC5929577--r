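# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so that constructors are deterministic without
#' disturbing the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

#' Split a master seed into a reproducible stream of sub-seeds
#'
#' All experiment-level randomness flows from one master seed; per-domain
#' and per-agent seeds are drawn from it with this fixed scheme. Seeds are
#' kept below 2^31 so they are valid R integers.
#'
#' @param master Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Numerically safe softmax over a numeric vector.
softmax <- function(x, beta = 1) {
  z <- beta * x
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Sample one index from a probability vector using the global RNG.
sample_categorical <- function(p) {
  u <- runif(1) * sum(p)
  cs <- cumsum(p)
  which.max(cs >= u)
}

# Clamp probabilities away from 0 (and 1) before taking logs.
PROB_FLOOR <- 1e-6

clamp_prob <- function(p) pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)

log2_safe <- function(p) log2(pmax(p, PROB_FLOOR))
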