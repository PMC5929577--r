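# Sequence-prediction analysis of context-popularity clustering. The CRP
# is used as a sequential predictor of a categorical sequence of reward
# functions X^R, either on its own (independent clustering) or with one
# predictor per observed transition label X^T (joint clustering), under
# the information-gain loss -log2 q of the realized label. Comparing the
# two accumulated losses as a function of the mutual information between
# the sequences, and of observation noise on X^T, delimits when each
# clustering strategy generalizes better.

#' Empirical mutual information between two aligned label sequences
#'
#' Plug-in estimate of `I(R; T) = sum Pr(R,T) log2 Pr(R,T)/(Pr(R)Pr(T))`
#' over aligned positions.
#'
#' @param seq_r,seq_t Character (or coercible) vectors of equal length.
#' @return Mutual information in bits; symmetric, and bounded by
#'   `min(H(R), H(T))`.
#' @export
mutual_information <- function(seq_r, seq_t) {
  seq_r <- as.character(seq_r); seq_t <- as.character(seq_t)
  if (length(seq_r) != length(seq_t)) stop("sequences must have equal length")
  if (length(seq_r) == 0) stop("sequences must be non-empty")
  jt <- table(seq_r, seq_t) / length(seq_r)
  pr <- rowSums(jt); pt <- colSums(jt)
  pos <- jt > 0
  sum(jt[pos] * log2(jt[pos] / outer(pr, pt)[pos]))
}

# Shannon entropy (bits) of a label vector's empirical distribution.
label_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

#' Construct the parametric mutual-information sequence pair
#'
#' `X^R = A^(2n) B^(2n)` and `X^T = 1^(n+m) 2^(2n) 1^(n-m)`, both of
#' length `4n`. The pair has `I(R; T) = 0` iff `m = 0`, and the mutual
#' information increases monotonically with `m`, holding the marginals
#' fixed.
#'
#' @param n Half-block size (sequence length is `4n`).
#' @param m Overlap shift, `0 <= m <= n`.
#' @return List with character vectors `seq_r` and `seq_t`.
#' @export
make_mi_sequences <- function(n, m) {
  if (m < 0 || m > n) stop("m must satisfy 0 <= m <= n")
  list(seq_r = c(rep("A", 2 * n), rep("B", 2 * n)),
       seq_t = c(rep("1", n + m), rep("2", 2 * n), rep("1", n - m)))
}

# One CRP predictor: score a label under counts, then the caller updates.
# Novel labels are scored with the new-cluster mass alpha/(N+alpha); when
# an alphabet is supplied that mass is spread uniformly over the labels
# not yet observed by this predictor (an open-world alphabet should
# include a catch-all bucket for never-listed labels).
crp_predict <- function(counts, total, label, alpha, alphabet) {
  n <- counts[label]
  if (!is.na(n) && n > 0) return(unname(n) / (total + alpha))
  q <- alpha / (total + alpha)
  if (!is.null(alphabet)) {
    n_unseen <- length(setdiff(alphabet, names(counts)[counts > 0]))
    q <- q / max(n_unseen, 1L)
  }
  q
}

#' Sequential CRP information gain of a sequence
#'
#' Scores each item with `-log2 q` under a CRP predictor over the labels
#' seen so far (counts updated after scoring): `q = N_l / (N + alpha)`
#' for a previously seen label, and the new-cluster mass `alpha/(N+alpha)`
#' for a novel one -- spread uniformly over not-yet-observed alphabet
#' labels when `alphabet` is supplied, otherwise taken whole (so the very
#' first item costs 0 bits).
#'
#' @param seq Label vector.
#' @param alpha CRP concentration.
#' @param alphabet Optional label universe for spreading new-cluster mass
#'   (include a catch-all label for an open world).
#' @return List with `total_bits` and the `per_item` bit trace.
#' @export
sequence_information_gain <- function(seq, alpha = 1, alphabet = NULL) {
  seq <- as.character(seq)
  counts <- numeric(0)
  total <- 0
  bits <- numeric(length(seq))
  for (i in seq_along(seq)) {
    x <- seq[i]
    bits[i] <- -log2(crp_predict(counts, total, x, alpha, alphabet))
    counts[x] <- if (is.na(counts[x])) 1 else counts[x] + 1
    total <- total + 1
  }
  list(total_bits = sum(bits), per_item = bits)
}

#' Conditional CRP information gain of X^R given X^T
#'
#' Maintains one CRP predictor per distinct observed transition label;
#' each reward label is scored (and then counted) under the predictor
#' indexed by its aligned -- possibly noise-corrupted -- transition label.
#' A never-seen transition label opens an empty predictor, which scores
#' with maximal ignorance under the novel-label convention of
#' [sequence_information_gain()].
#'
#' @param seq_r,seq_t Aligned label vectors.
#' @inheritParams sequence_information_gain
#' @return List with `total_bits` and `per_item`.
#' @export
conditional_information_gain <- function(seq_r, seq_t, alpha = 1,
                                         alphabet = NULL) {
  seq_r <- as.character(seq_r); seq_t <- as.character(seq_t)
  if (length(seq_r) != length(seq_t)) stop("sequences must have equal length")
  counts <- list()
  totals <- numeric(0)
  bits <- numeric(length(seq_r))
  for (i in seq_along(seq_r)) {
    tl <- seq_t[i]; x <- seq_r[i]
    if (is.null(counts[[tl]])) { counts[[tl]] <- numeric(0); totals[tl] <- 0 }
    bits[i] <- -log2(crp_predict(counts[[tl]], totals[[tl]], x, alpha, alphabet))
    counts[[tl]][x] <- if (is.na(counts[[tl]][x])) 1 else counts[[tl]][x] + 1
    totals[tl] <- totals[tl] + 1
  }
  list(total_bits = sum(bits), per_item = bits)
}

#' Corrupt a transition sequence with novel-label observation noise
#'
#' Each item is independently mis-identified with probability `sigma` as a
#' label outside the sequence's alphabet. By default every corrupted
#' observation receives its own globally fresh label; with
#' `shared = TRUE` all corrupted observations within the call receive the
#' same novel label `T*` (one unrecognized function). Noise alters only
#' the observations, never the generative relationship between the
#' sequences.
#'
#' @param seq_t Label vector.
#' @param sigma Corruption probability in `[0, 1]`.
#' @param shared Use a single shared novel label for all corrupted items.
#' @return Corrupted label vector.
#' @export
apply_noise <- function(seq_t, sigma, shared = FALSE) {
  stopifnot(sigma >= 0, sigma <= 1)
  seq_t <- as.character(seq_t)
  hit <- runif(length(seq_t)) < sigma
  if (any(hit)) {
    seq_t[hit] <- if (shared) "Tstar" else paste0("Tstar", seq_len(sum(hit)))
  }
  seq_t
}

#' Bias of the CRP as an estimator of the generative distribution
#'
#' `Bias = E[q] - p = -alpha / (alpha + N_c)`; vanishes as the number of
#' observed contexts grows.
#'
#' @param alpha CRP concentration (> 0).
#' @param n_contexts Number of observed contexts (>= 0).
#' @return Signed bias.
#' @export
crp_bias <- function(alpha, n_contexts) {
  stopifnot(alpha > 0, n_contexts >= 0)
  -alpha / (alpha + n_contexts)
}

#' Information gain of a naive uniform guess
#'
#' Every item costs `log2 |alphabet|` bits under a uniform guess over a
#' known label set.
#'
#' @param seq Label vector.
#' @param alphabet Label universe covering every label in `seq`.
#' @return Total bits.
#' @export
naive_information_gain <- function(seq, alphabet) {
  seq <- as.character(seq)
  if (!all(seq %in% alphabet)) stop("sequence contains labels outside the alphabet")
  length(seq) * log2(length(alphabet))
}

#' Independent-vs-joint advantage across the mutual-information sweep
#'
#' For each `m` builds the [make_mi_sequences()] pair and compares the
#' marginal CRP prediction of `X^R` (independent clustering) with the
#' conditional prediction given `X^T` (joint clustering), in total bits.
#' Positive advantage means independent clustering predicts the reward
#' sequence at lower information cost. Deterministic (no noise). The
#' alphabet is the reward label set plus a catch-all bucket.
#'
#' @param n Half-block size (default 5).
#' @param m_values Shift values (default `0:n`).
#' @param alpha CRP concentration.
#' @return Data frame with columns `m`, `mutual_information`,
#'   `marginal_bits`, `conditional_bits`, `independent_advantage`.
#' @export
mi_sweep <- function(n = 5, m_values = 0:n, alpha = 1) {
  alphabet <- c("A", "B", "other")
  rows <- lapply(m_values, function(m) {
    s <- make_mi_sequences(n, m)
    marg <- sequence_information_gain(s$seq_r, alpha, alphabet)$total_bits
    cond <- conditional_information_gain(s$seq_r, s$seq_t, alpha, alphabet)$total_bits
    data.frame(m = m, mutual_information = mutual_information(s$seq_r, s$seq_t),
               marginal_bits = marg, conditional_bits = cond,
               independent_advantage = cond - marg)
  })
  do.call(rbind, rows)
}

#' Noise sweep: independent-vs-joint advantage under corrupted mappings
#'
#' Monte-Carlo estimate of the mean conditional (joint) information cost
#' of predicting `X^R` when each observation of `X^T` is mis-identified
#' as one unrecognized novel function `T*` with probability sigma,
#' compared against the noise-free marginal (independent) cost. Uses the
#' perfect-correspondence pair `X^R = A^(20)BCD`, `X^T = 1^(20)234`, or
#' the shifted pair `X^T = 1^(19)2341` with residual uncertainty.
#'
#' @param sigmas Noise levels to evaluate.
#' @param n_rep Monte-Carlo replicates per level.
#' @param shifted Use the shifted (lower mutual information) pair.
#' @param alpha CRP concentration.
#' @param seed Integer seed.
#' @return Data frame with `sigma`, `marginal_bits`, `conditional_bits`
#'   (Monte-Carlo mean) and `independent_advantage`.
#' @export
noise_sweep <- function(sigmas = seq(0, 1, 0.05), n_rep = 10000,
                        shifted = FALSE, alpha = 1, seed = 1L) {
  seq_r <- c(rep("A", 20), "B", "C", "D")
  seq_t <- if (shifted) c(rep("1", 19), "2", "3", "4", "1")
           else c(rep("1", 20), "2", "3", "4")
  alphabet <- c("A", "B", "C", "D", "other")
  marg <- sequence_information_gain(seq_r, alpha, alphabet)$total_bits
  set.seed(seed)
  rows <- lapply(sigmas, function(s) {
    cond <- mean(vapply(seq_len(n_rep), function(i) {
      conditional_information_gain(seq_r, apply_noise(seq_t, s, shared = TRUE),
                                   alpha, alphabet)$total_bits
    }, numeric(1)))
    data.frame(sigma = s, marginal_bits = marg, conditional_bits = cond,
               independent_advantage = cond - marg)
  })
  do.call(rbind, rows)
}

#' Locate the noise level where the two strategies break even
#'
#' Linear interpolation of the first sign change of
#' `independent_advantage` across a [noise_sweep()] result.
#'
#' @param sweep Data frame from [noise_sweep()].
#' @return The crossover sigma, or `NA` if the advantage never changes
#'   sign.
#' @export
noise_crossover <- function(sweep) {
  adv <- sweep$independent_advantage
  s <- sweep$sigma
  i <- which(adv[-length(adv)] < 0 & adv[-1] >= 0)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  s[i] + (s[i + 1] - s[i]) * (-adv[i]) / (adv[i + 1] - adv[i])
}
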