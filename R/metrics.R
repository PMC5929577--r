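# Evaluation metrics: divergence of learned function estimates from the
# truth, and the conditional mutual information between goals and mapping
# clusters that the meta-agent's strategy choice tracks.

#' KL divergence of a function estimate from the truth
#'
#' For mappings: the mean over the eight actions of
#' `D_KL(truth(. | a) || phi_hat(. | a))`, where the truth puts mass 1 on
#' the action's true movement. For rewards: the mean over cells of the
#' Bernoulli divergence `D_KL(truth(x) || Rhat(x))`. Estimates are floored
#' at 1e-6 before taking logs.
#'
#' @param estimate For `kind = "mapping"`, an 8x4 row-stochastic matrix;
#'   for `kind = "reward"`, a per-cell probability vector.
#' @param truth For `kind = "mapping"`, either the true mapping as an
#'   integer vector of movement indices or an 8x4 one-hot matrix; for
#'   `kind = "reward"`, a per-cell 0/1 vector.
#' @param kind `"mapping"` or `"reward"`.
#' @return Divergence in bits (non-negative).
#' @export
kl_to_truth <- function(estimate, truth, kind = c("mapping", "reward")) {
  kind <- match.arg(kind)
  if (kind == "mapping") {
    if (is.matrix(truth)) truth <- apply(truth, 1, which.max)
    stopifnot(nrow(estimate) == length(truth))
    mean(-log2_safe(estimate[cbind(seq_along(truth), truth)]))
  } else {
    stopifnot(length(estimate) == length(truth))
    p <- truth
    q <- pmin(pmax(estimate, PROB_FLOOR), 1 - PROB_FLOOR)
    terms <- ifelse(p == 1, -log2(q), -log2(1 - q))  # Bernoulli KL, truth 0/1
    mean(terms)
  }
}

#' Conditional mutual information between goals and mapping clusters
#'
#' `I(R; Phi | D) = H(Pr(R | D)) - H(Pr(R | phi = phi_k, D))`: the entropy
#' of the empirical goal-location distribution over all contexts whose
#' goal has been observed, minus the entropy of that distribution
#' restricted to contexts sharing the query context's MAP mapping cluster.
#' If no context in the cluster has an observed goal, the restricted
#' distribution is taken to be the marginal (no information, 0 bits).
#'
#' @param goals Named integer vector: the observed goal cell per context,
#'   `NA` where the goal has not been found yet.
#' @param mapping_cluster Named integer vector: MAP mapping-cluster id per
#'   context (must cover `context`).
#' @param context The context whose cluster conditions the second term.
#' @return Mutual information in bits, or `NA` (with a warning) when no
#'   goal has been observed in any context.
#' @export
conditional_goal_mi <- function(goals, mapping_cluster, context) {
  seen <- names(goals)[!is.na(goals)]
  if (length(seen) == 0) {
    warning("no observed goals; conditional mutual information undefined")
    return(NA_real_)
  }
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  h_marg <- ent(goals[seen])
  k <- mapping_cluster[[context]]
  members <- intersect(seen, names(mapping_cluster)[mapping_cluster == k])
  h_cond <- if (length(members) == 0) h_marg else ent(goals[members])
  h_marg - h_cond
}
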