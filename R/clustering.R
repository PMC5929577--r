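# CRP-prior partition inference over contexts. A belief state holds a set
# of partition hypotheses, each with per-cluster sufficient statistics for
# the mapping function (action x movement counts) and/or the reward
# function (per-location Beta pseudo-counts). Hypotheses accumulate the
# sequential posterior-predictive log probability of every observation;
# low-probability hypotheses are pruned relative to the MAP.

MAPPING_EPS <- 0.01   # Dirichlet pseudo-count per (action, movement)
REWARD_S0 <- 0.01     # optimistic Beta(0.01, 0) prior: Rhat = 1 before data

#' Chinese restaurant process assignment prior
#'
#' Probability that a new context joins cluster `target` given current
#' cluster occupancies: `N_k / (N + alpha)` for an existing cluster,
#' `alpha / (N + alpha)` for the new cluster (`target = length(counts) + 1`).
#'
#' @param counts Integer vector of contexts per existing cluster.
#' @param alpha Concentration parameter (> 0).
#' @param target Cluster index; `length(counts) + 1` denotes a new cluster.
#' @return Probability in `[0, 1]`.
#' @export
crp_assignment_prior <- function(counts, alpha, target) {
  stopifnot(alpha > 0, all(counts >= 0))
  n <- sum(counts)
  k <- length(counts)
  if (target >= 1 && target <= k) counts[target] / (n + alpha)
  else if (target == k + 1) alpha / (n + alpha)
  else stop("invalid cluster index: ", target)
}

#' Create an empty belief state
#'
#' @param mode One of `"joint"` (one partition whose clusters carry both
#'   mapping and reward statistics), `"mapping"` or `"reward"` (one
#'   partition carrying a single statistic, used in pairs by the
#'   independent agent), or `"flat"` (a single hypothesis in which every
#'   context is its own cluster; no generalization).
#' @param alpha CRP concentration parameter.
#' @param n_cells Number of grid cells covered by reward statistics.
#' @param prune_ratio Hypotheses with posterior below `prune_ratio` times
#'   the MAP posterior are discarded (0 disables pruning).
#' @return An object of class `belief_state`.
#' @export
new_belief <- function(mode = c("joint", "mapping", "reward", "flat"),
                       alpha = 1, n_cells = 36L, prune_ratio = 0.1) {
  mode <- match.arg(mode)
  structure(list(mode = mode, alpha = alpha, n_cells = as.integer(n_cells),
                 prune_ratio = prune_ratio, contexts = character(0),
                 hyps = list(), next_id = 1L),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state %s: %d contexts, %d hypotheses, alpha=%g>\n",
              x$mode, length(x$contexts), length(x$hyps), x$alpha))
  invisible(x)
}

track_map <- function(belief) belief$mode %in% c("joint", "mapping", "flat")
track_rew <- function(belief) belief$mode %in% c("joint", "reward", "flat")

empty_cluster <- function(belief) {
  cl <- list()
  if (track_map(belief)) cl$map <- matrix(0, N_ACTIONS, 4L)
  if (track_rew(belief)) {
    cl$rs <- rep(REWARD_S0, belief$n_cells)
    cl$rf <- rep(0, belief$n_cells)
  }
  cl
}

new_hypothesis <- function(id) {
  list(assign = integer(0), sizes = integer(0), clusters = list(),
       lp = 0, ll = 0, id = id)
}

hyp_child <- function(belief, h, context_id, k, id) {
  n <- length(h$assign)
  kmax <- length(h$sizes)
  if (k <= kmax) {
    h$lp <- h$lp + log(h$sizes[k] / (n + belief$alpha))
    h$sizes[k] <- h$sizes[k] + 1L
  } else {
    h$lp <- h$lp + log(belief$alpha / (n + belief$alpha))
    h$sizes <- c(h$sizes, 1L)
    h$clusters[[k]] <- empty_cluster(belief)
  }
  h$assign[context_id] <- k
  h$id <- id
  h
}

#' Augment the hypothesis space with a new context
#'
#' Every hypothesis spawns one child per existing cluster plus one for a
#' new cluster, extending the sequential CRP prior product; accumulated
#' likelihoods are unchanged. In flat mode the single hypothesis simply
#' assigns the context its own cluster. Pruning is applied afterwards.
#'
#' @param belief A `belief_state`.
#' @param context_id Previously unseen context identifier.
#' @return The augmented `belief_state`.
#' @export
augment_on_new_context <- function(belief, context_id) {
  if (context_id %in% belief$contexts) stop("duplicate context: ", context_id)
  belief$contexts <- c(belief$contexts, context_id)
  if (length(belief$hyps) == 0) belief$hyps <- list(new_hypothesis(0L))
  if (belief$mode == "flat") {
    h <- belief$hyps[[1]]
    belief$hyps[[1]] <- hyp_child(belief, h, context_id, length(h$sizes) + 1L,
                                  belief$next_id)
    belief$next_id <- belief$next_id + 1L
    return(belief)
  }
  children <- list()
  id <- belief$next_id
  for (h in belief$hyps) {
    for (k in seq_len(length(h$sizes) + 1L)) {
      children[[length(children) + 1L]] <- hyp_child(belief, h, context_id, k, id)
      id <- id + 1L
    }
  }
  belief$next_id <- id
  belief$hyps <- children
  prune_hypotheses(belief)
}

# Posterior-predictive probability of a mapping event (a, A) under a
# cluster's Dirichlet-smoothed counts.
mapping_predictive <- function(map_counts, action, movement) {
  (map_counts[action, movement] + MAPPING_EPS) /
    (sum(map_counts[action, ]) + 4 * MAPPING_EPS)
}

#' Information gained from one mapping observation
#'
#' The information-gain loss `-log2` of the cluster's predictive
#' probability of the observed (action, movement) event. For a fresh
#' cluster the predictive is uniform over the four movements, so the first
#' action observed in a novel context yields exactly 2 bits.
#'
#' @param map_counts 8x4 matrix of observed (action, movement) counts
#'   (e.g. from a fresh cluster: all zeros).
#' @param action Action index in 1..8.
#' @param movement Movement index in 1..4.
#' @return Bits of information.
#' @export
mapping_observation_bits <- function(map_counts, action, movement) {
  -log2(mapping_predictive(map_counts, action, movement))
}

#' Update every hypothesis with one observation
#'
#' For each hypothesis the cluster assigned to the context absorbs the
#' observation into its counts and the observation is then scored under
#' the cluster's maximum-likelihood estimate (Dirichlet-smoothed movement
#' probabilities for mapping events, the Beta-mean Bernoulli probability
#' for reward events, floored at 1e-6); the log likelihood accumulates.
#' Scoring under the estimate that includes the observation keeps the
#' accumulated likelihood exchangeable and gives clustering its
#' characteristic dynamics: hypotheses are drawn together by the CRP
#' popularity prior and pushed apart only by contradicted predictions (a
#' fresh cluster explains any single observation almost perfectly, while
#' a cluster that confidently predicted the opposite event pays a large
#' penalty). Mapping-only and reward-only beliefs score one event type;
#' joint and flat beliefs score both in one partition. Pruning is applied
#' afterwards.
#'
#' @param belief A `belief_state` already containing `context_id`.
#' @param context_id Context the observation was made in.
#' @param action,movement Mapping event: action index and observed
#'   movement index (both NULL to skip).
#' @param cell,reward Reward event: cell entered and binary reward
#'   observed there (both NULL to skip).
#' @return The updated `belief_state`.
#' @export
update_likelihood <- function(belief, context_id, action = NULL,
                              movement = NULL, cell = NULL, reward = NULL) {
  do_map <- track_map(belief) && !is.null(action)
  do_rew <- track_rew(belief) && !is.null(cell)
  if (!do_map && !do_rew) {
    if (!is.null(action) || !is.null(cell))
      stop("observation type inconsistent with belief mode ", belief$mode)
    return(belief)
  }
  hyps <- belief$hyps
  for (i in seq_along(hyps)) {
    h <- hyps[[i]]
    k <- h$assign[[context_id]]
    cl <- h$clusters[[k]]
    if (do_map) {
      cl$map[action, movement] <- cl$map[action, movement] + 1
      p <- mapping_predictive(cl$map, action, movement)
      h$ll <- h$ll + log(p)
    }
    if (do_rew) {
      cl$rs[cell] <- cl$rs[cell] + reward
      cl$rf[cell] <- cl$rf[cell] + (1 - reward)
      phat <- cl$rs[cell] / (cl$rs[cell] + cl$rf[cell])
      pr <- if (reward == 1) phat else 1 - phat
      h$ll <- h$ll + log(max(pr, PROB_FLOOR))
    }
    h$clusters[[k]] <- cl
    hyps[[i]] <- h
  }
  belief$hyps <- hyps
  prune_hypotheses(belief)
}

# Drop hypotheses whose posterior falls below prune_ratio times the MAP
# posterior.
prune_hypotheses <- function(belief) {
  if (belief$prune_ratio <= 0 || length(belief$hyps) <= 1) return(belief)
  lpost <- vapply(belief$hyps, function(h) h$lp + h$ll, numeric(1))
  keep <- lpost >= max(lpost) + log(belief$prune_ratio)
  belief$hyps <- belief$hyps[keep]
  belief
}

#' Normalized posterior over hypotheses
#'
#' @param belief A `belief_state`.
#' @return Numeric vector summing to 1, in hypothesis order.
#' @export
belief_posteriors <- function(belief) {
  lpost <- vapply(belief$hyps, function(h) h$lp + h$ll, numeric(1))
  w <- exp(lpost - max(lpost))
  w / sum(w)
}

#' Extract the MAP hypothesis
#'
#' Returns the hypothesis with the highest posterior; ties are broken in
#' favor of the earliest-created hypothesis.
#'
#' @param belief A `belief_state` with at least one hypothesis.
#' @return A hypothesis (list with `assign`, `sizes`, `clusters`, `lp`,
#'   `ll`, `id`).
#' @export
map_hypothesis <- function(belief) {
  if (length(belief$hyps) == 0) stop("belief state holds no hypotheses")
  lpost <- vapply(belief$hyps, function(h) h$lp + h$ll, numeric(1))
  ids <- vapply(belief$hyps, function(h) h$id, integer(1))
  best <- which(lpost == max(lpost))
  belief$hyps[[best[which.min(ids[best])]]]
}

#' Context-to-cluster table of the MAP hypothesis
#'
#' @param belief A `belief_state`.
#' @return Data frame with columns `context_id` and `cluster`.
#' @export
belief_partition <- function(belief) {
  h <- map_hypothesis(belief)
  data.frame(context_id = names(h$assign), cluster = unname(h$assign),
             stringsAsFactors = FALSE)
}

# Estimated mapping table (8x4, rows sum to 1) of the cluster a context is
# assigned to under hypothesis h.
cluster_phi_hat <- function(h, context_id) {
  m <- h$clusters[[h$assign[[context_id]]]]$map
  sm <- (m + MAPPING_EPS)
  sm / rowSums(sm)
}

# Estimated reward probability per cell for a context's cluster under h.
cluster_r_hat <- function(h, context_id) {
  cl <- h$clusters[[h$assign[[context_id]]]]
  cl$rs / (cl$rs + cl$rf)
}
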