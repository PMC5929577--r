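# Model-based planning: value iteration over the known spatial kernel and
# an estimated reward function, a softmax policy over cardinal movements,
# and marginalization through the estimated mapping down to primitive
# actions.

#' Planner configuration
#'
#' @param gamma Discount factor in (0, 1).
#' @param beta Softmax inverse temperature (>= 0).
#' @param tol Value-iteration convergence threshold on the Bellman
#'   residual.
#' @param max_iter Iteration cap.
#' @return A list of class `plan_config`.
#' @export
plan_config <- function(gamma = 0.75, beta = 5.0, tol = 1e-5, max_iter = 500L) {
  stopifnot(gamma > 0, gamma < 1, beta >= 0, tol > 0)
  structure(list(gamma = gamma, beta = beta, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "plan_config")
}

#' Solve the navigation MDP by value iteration
#'
#' The value function treats reward as terminating: the backup is
#' `V(x) = max_A [ Rhat(x') + gamma * (1 - Rhat(x')) * V(x') ]` with `x'`
#' the clamped successor of `x` under movement `A`, reading the reward
#' estimate as the probability that entering a cell pays (and thereby ends
#' the trial). With a point goal (`Rhat` 1 at the goal, 0 elsewhere) the
#' fixed point is the geometric field `V(x) = gamma^(d(x) - 1)` with `d`
#' the Manhattan distance to the goal. The movement values used for action
#' selection are then assembled as `Q(x, A) = Rhat(x') + gamma * V(x')`:
#' the episodic value keeps the field bounded and goal-anchored, while the
#' undiminished continuation term gives the softmax a contrast between
#' reward-adjacent and remote movements commensurate with the reward
#' magnitude.
#'
#' @param reward_hat Numeric vector of estimated reward probabilities per
#'   cell (length `grid$n_cells`).
#' @param grid A [grid_spec()].
#' @param config A [plan_config()].
#' @param v0 Optional warm-start value vector.
#' @param terminal Optional logical/0-1 vector marking cells the agent
#'   knows to end the episode whatever the reward (the door cells of the
#'   rooms task); no continuation value flows through them.
#' @return A list of class `plan_result` with `V` (per cell), `Q`
#'   (`n_cells` x 4 matrix over movements), `iterations` and `converged`.
#' @export
value_iteration <- function(reward_hat, grid, config = plan_config(),
                            v0 = NULL, terminal = NULL) {
  stopifnot(length(reward_hat) == grid$n_cells)
  if (is.null(v0)) v0 <- numeric(grid$n_cells)
  if (is.null(terminal)) terminal <- numeric(grid$n_cells)
  reward_hat <- as.numeric(reward_hat)
  cont <- 1 - as.numeric(terminal)
  out <- .vi_cpp(reward_hat, grid$succ, config$gamma,
                 config$tol, config$max_iter, as.numeric(v0),
                 as.numeric(terminal))
  if (!out$converged)
    stop(sprintf("value iteration did not converge in %d iterations (residual %.3g)",
                 out$iterations, out$residual))
  out$Q <- matrix(reward_hat[grid$succ], ncol = 4L) +
    config$gamma * matrix((cont * out$V)[grid$succ], ncol = 4L)
  colnames(out$Q) <- MOVEMENT_NAMES
  class(out) <- "plan_result"
  out
}

#' Softmax policy over cardinal movements
#'
#' `Pr(A | x) = exp(beta Q(x, A)) / sum_A' exp(beta Q(x, A'))`.
#'
#' @param plan A `plan_result` from [value_iteration()].
#' @param cell Cell index.
#' @param beta Inverse temperature.
#' @return Probability vector over the four movements.
#' @export
movement_policy <- function(plan, cell, beta) {
  setNames(softmax(plan$Q[cell, ], beta), MOVEMENT_NAMES)
}

#' Marginalize a movement policy to primitive actions
#'
#' `Pr(a | x)` proportional to `sum_A phi_hat(A | a) Pr(A | x)`,
#' renormalized to a proper distribution over the eight actions. With the
#' mapping known and deterministic this is uniform over the actions that
#' produce the selected movement; with a fully uninformed mapping it is
#' uniform over all eight actions.
#'
#' @param movement_probs Probability vector over the four movements.
#' @param phi_hat 8x4 matrix of estimated movement probabilities per
#'   action (rows sum to 1).
#' @return Probability vector over the eight actions.
#' @export
primitive_action_policy <- function(movement_probs, phi_hat) {
  p <- as.numeric(phi_hat %*% movement_probs)
  p / sum(p)
}
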