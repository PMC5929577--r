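# Mapping functions: total assignments of the 8 primitive actions to the 4
# cardinal movements, balanced so that exactly two actions produce each
# movement. Orthogonal sets (mappings that disagree on every action) are
# built from a Latin square over action pairs.

#' Build a set of mutually orthogonal balanced mappings
#'
#' Actions are grouped into four pairs; a seeded random 4x4 Latin square
#' over movements assigns each pair a movement per mapping. Distinct rows
#' of a Latin square disagree in every column, so any two mappings in the
#' set disagree on all eight actions (orthogonality), and each mapping
#' sends exactly two actions to each movement (balance).
#'
#' @param n_mappings Number of mappings, between 1 and 4.
#' @param seed Integer seed controlling the pairing of actions and the
#'   Latin square.
#' @return A list of `n_mappings` integer vectors of length 8; entry `a`
#'   is the movement index (1=North, 2=South, 3=East, 4=West) produced by
#'   action `a`. Vectors carry names `a1`..`a8`.
#' @export
make_orthogonal_mappings <- function(n_mappings, seed) {
  stopifnot(n_mappings >= 1, n_mappings <= 4)
  with_seed(seed, {
    pairs <- matrix(sample.int(N_ACTIONS), nrow = 4L)  # rows: action pairs
    base <- outer(0:3, 0:3, function(i, j) (i + j) %% 4L) + 1L  # cyclic square
    sq <- base[sample.int(4L), sample.int(4L)]
    perm <- sample.int(4L)  # relabel movements
    lapply(seq_len(n_mappings), function(i) {
      map <- integer(N_ACTIONS)
      for (j in 1:4) map[pairs[j, ]] <- perm[sq[i, j]]
      names(map) <- paste0("a", seq_len(N_ACTIONS))
      map
    })
  })
}

#' Test whether two mappings are orthogonal
#'
#' Two mappings are orthogonal iff they disagree on every primitive action.
#'
#' @param m1,m2 Integer mapping vectors as returned by
#'   [make_orthogonal_mappings()].
#' @return Logical scalar.
#' @export
mappings_orthogonal <- function(m1, m2) all(m1 != m2)

# Balance check used by tests and validators.
mapping_balanced <- function(m) all(tabulate(m, nbins = 4L) == 2L)
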