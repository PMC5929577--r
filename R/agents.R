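# Full agent loops. An agent couples belief states over context partitions
# (flat, independent, or joint) with per-step model-based planning: infer
# the MAP hypothesis, run value iteration on its reward estimate, soften
# the movement values with beta, marginalize through the estimated mapping
# to primitive actions, act, observe, update.

#' Agent configuration
#'
#' Defaults are the common parameter set used throughout the grid-world
#' simulations: gamma = 0.75, beta = 5.0, alpha = 1.0 (the rooms task uses
#' gamma = 0.80), eta = 0.2 for the RL arbitration heuristic.
#'
#' @param gamma Discount factor.
#' @param beta Softmax inverse temperature (movement selection, and model
#'   selection for the RL meta-agent).
#' @param alpha CRP concentration parameter.
#' @param eta Learning rate of the RL meta-agent.
#' @param prune_ratio Hypothesis pruning threshold relative to the MAP.
#' @param tol,max_iter Value-iteration convergence controls.
#' @param step_cap Per-trial safety cap on steps; exceeding it is an error.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(gamma = 0.75, beta = 5.0, alpha = 1.0, eta = 0.2,
                         prune_ratio = 0.1, tol = 1e-5, max_iter = 500L,
                         step_cap = 10000L) {
  structure(list(gamma = gamma, beta = beta, alpha = alpha, eta = eta,
                 prune_ratio = prune_ratio, tol = tol,
                 max_iter = as.integer(max_iter),
                 step_cap = as.integer(step_cap)),
            class = "agent_config")
}

AGENT_KINDS <- c("flat", "independent", "joint", "meta_bayes", "meta_rl")

# ---- clustering models ----------------------------------------------------
# A "model" is the belief machinery of one fixed strategy. The independent
# model holds two partitions (mapping and reward); the joint and flat
# models hold one partition carrying both statistics.

model_new <- function(kind, alpha, n_cells, prune_ratio) {
  switch(kind,
    flat = list(kind = "flat",
                belief = new_belief("flat", alpha, n_cells, prune_ratio)),
    independent = list(kind = "independent",
                       map_belief = new_belief("mapping", alpha, n_cells, prune_ratio),
                       rew_belief = new_belief("reward", alpha, n_cells, prune_ratio)),
    joint = list(kind = "joint",
                 belief = new_belief("joint", alpha, n_cells, prune_ratio)),
    stop("unknown model kind: ", kind))
}

model_add_context <- function(model, ctx) {
  if (model$kind == "independent") {
    model$map_belief <- augment_on_new_context(model$map_belief, ctx)
    model$rew_belief <- augment_on_new_context(model$rew_belief, ctx)
  } else {
    model$belief <- augment_on_new_context(model$belief, ctx)
  }
  model
}

model_knows_context <- function(model, ctx) {
  b <- if (model$kind == "independent") model$map_belief else model$belief
  ctx %in% b$contexts
}

model_update <- function(model, ctx, action, movement, cell, reward) {
  if (model$kind == "independent") {
    model$map_belief <- update_likelihood(model$map_belief, ctx,
                                          action = action, movement = movement)
    model$rew_belief <- update_likelihood(model$rew_belief, ctx,
                                          cell = cell, reward = reward)
  } else {
    model$belief <- update_likelihood(model$belief, ctx, action = action,
                                      movement = movement, cell = cell,
                                      reward = reward)
  }
  model
}

# MAP estimates used for planning in a context: phi (8x4) and rhat (cells).
model_estimates <- function(model, ctx) {
  if (model$kind == "independent") {
    list(phi = cluster_phi_hat(map_hypothesis(model$map_belief), ctx),
         rhat = cluster_r_hat(map_hypothesis(model$rew_belief), ctx))
  } else {
    h <- map_hypothesis(model$belief)
    list(phi = cluster_phi_hat(h, ctx), rhat = cluster_r_hat(h, ctx))
  }
}

# MAP probability that entering `cell` in `ctx` pays reward 1.
model_predict_reward <- function(model, ctx, cell) {
  h <- map_hypothesis(if (model$kind == "independent") model$rew_belief
                      else model$belief)
  cl <- h$clusters[[h$assign[[ctx]]]]
  cl$rs[cell] / (cl$rs[cell] + cl$rf[cell])
}

# Mapping-partition MAP assignment (used for the conditional-MI trace).
model_mapping_partition <- function(model) {
  b <- switch(model$kind, independent = model$map_belief, model$belief)
  map_hypothesis(b)$assign
}

# ---- meta arbitration ------------------------------------------------------

#' Sample the acting model by Thompson sampling over model evidence
#'
#' Selection probability is proportional to `exp(log_evidence) * prior`.
#'
#' @param log_evidence Named numeric vector of accumulated log model
#'   evidence (reward-prediction log probabilities).
#' @param prior Prior over models (same names); uniform by default.
#' @return Name of the sampled model.
#' @export
meta_select_model <- function(log_evidence, prior = NULL) {
  if (is.null(prior)) prior <- rep(1 / length(log_evidence), length(log_evidence))
  p <- meta_responsibilities(log_evidence, prior)
  names(log_evidence)[sample_categorical(p)]
}

#' Posterior responsibilities of the meta-agent's models
#'
#' @inheritParams meta_select_model
#' @return Probability vector over models.
#' @export
meta_responsibilities <- function(log_evidence, prior = NULL) {
  if (is.null(prior)) prior <- rep(1 / length(log_evidence), length(log_evidence))
  z <- log_evidence + log(prior)
  w <- exp(z - max(z))
  setNames(w / sum(w), names(log_evidence))
}

#' Accumulate reward-prediction model evidence
#'
#' Adds `log Pr(r_t | m)` for each model, with the same 1e-6 floor used in
#' the clustering likelihoods.
#'
#' @param log_evidence Named numeric vector of accumulated log evidence.
#' @param reward Observed binary reward.
#' @param predictions Named vector of each model's MAP probability that
#'   the entered cell pays reward 1.
#' @return Updated `log_evidence`.
#' @export
meta_update_evidence <- function(log_evidence, reward, predictions) {
  pr <- if (reward == 1) predictions else 1 - predictions
  log_evidence + log(pmax(pr, PROB_FLOOR))
}

#' One RL-heuristic arbitration update
#'
#' Applies the prediction-error update `Q_m <- Q_m + eta * (r_t - rhat_t)`
#' to the active model only, and samples the next model from
#' `softmax(beta * Q)`.
#'
#' @param q Named numeric vector of model values.
#' @param active Name of the model whose policy was in control.
#' @param reward Observed binary reward.
#' @param prediction The active model's predicted reward at the entered
#'   cell.
#' @param eta Learning rate in (0, 1].
#' @param beta Inverse temperature for model sampling.
#' @return List with updated `q` and the `sampled` model name.
#' @export
rl_meta_step <- function(q, active, reward, prediction, eta, beta) {
  stopifnot(eta > 0, eta <= 1)
  q[active] <- q[active] + eta * (reward - prediction)
  list(q = q, sampled = names(q)[sample_categorical(softmax(q, beta))])
}

# ---- episode loop ----------------------------------------------------------

#' Run an agent through all trials of a task domain
#'
#' Executes the domain's seeded trial sequence. Per step the agent plans
#' from the MAP hypothesis (value iteration, warm-started), samples a
#' cardinal movement by softmax and a primitive action through the
#' estimated mapping, observes the outcome, and updates its beliefs. Meta
#' agents maintain both the independent and joint models, update both (and
#' their reward-prediction evidence) every step, and select the acting
#' model once per trial -- by Thompson sampling on accumulated evidence
#' (`meta_bayes`) or by softmax on prediction-error values (`meta_rl`).
#'
#' @param domain A `task_domain`.
#' @param agent One of `"flat"`, `"independent"`, `"joint"`,
#'   `"meta_bayes"`, `"meta_rl"`.
#' @param config An [agent_config()].
#' @param seed Integer seed for the agent's action/start randomness.
#' @param record_kl If TRUE, record per-trial KL divergence of the acting
#'   model's reward and mapping estimates from the truth, measured at
#'   trial start (the generalization available on entering the context).
#' @param record_steps If TRUE, keep the full trajectory as a tidy data
#'   frame (`trial`, `context`, `step`, `x`, `y`, `action`, `movement`,
#'   `reward`) in the returned record.
#' @return A list of class `run_record`: `agent`, `seed`, `total_steps`,
#'   `trials` (data frame with per-trial steps and, for meta agents, the
#'   acting model and joint-selection probability), `kl` (data frame or
#'   NULL), and for meta agents `mi_choice` (conditional mutual
#'   information at each context onset paired with the end-of-trial
#'   probability of selecting the joint model).
#' @export
run_episode <- function(domain, agent = AGENT_KINDS, config = agent_config(),
                        seed = 1L, record_kl = FALSE, record_steps = FALSE) {
  agent <- match.arg(agent)
  set.seed(seed)
  grid <- domain$grid
  n_cells <- grid$n_cells
  pconf <- plan_config(config$gamma, config$beta, config$tol, config$max_iter)
  is_meta <- agent %in% c("meta_bayes", "meta_rl")
  models <- if (is_meta) {
    list(independent = model_new("independent", config$alpha, n_cells, config$prune_ratio),
         joint = model_new("joint", config$alpha, n_cells, config$prune_ratio))
  } else {
    setNames(list(model_new(agent, config$alpha, n_cells, config$prune_ratio)), agent)
  }
  log_ev <- c(independent = 0, joint = 0)
  q_meta <- c(independent = 0, joint = 0)
  warm <- lapply(models, function(m) numeric(n_cells))

  # precomputed truth per context (for the environment and KL metrics)
  ctx_ids <- domain$contexts$context_id
  goal_of <- setNames(vapply(ctx_ids, function(cc) context_goal(domain, cc), integer(1)), ctx_ids)
  map_of <- setNames(lapply(ctx_ids, function(cc) context_mapping(domain, cc)), ctx_ids)

  n_trials <- length(domain$trial_seq)
  tr_steps <- integer(n_trials)
  tr_model <- character(n_trials)
  tr_pjoint <- rep(NA_real_, n_trials)
  seen_count <- setNames(integer(length(ctx_ids)), ctx_ids)
  goal_found <- setNames(rep(NA_integer_, length(ctx_ids)), ctx_ids)
  kl_rows <- if (record_kl) vector("list", n_trials) else NULL
  step_rows <- if (record_steps) vector("list", n_trials) else NULL
  mi_rows <- list()

  for (t in seq_len(n_trials)) {
    ctx <- domain$trial_seq[t]
    new_ctx <- !model_knows_context(models[[1]], ctx)
    if (new_ctx) {
      models <- lapply(models, model_add_context, ctx = ctx)
      if (is_meta) {
        cmi <- if (all(is.na(goal_found))) NA_real_ else
          conditional_goal_mi(goal_found,
                              model_mapping_partition(models$independent), ctx)
        mi_rows[[length(mi_rows) + 1L]] <-
          data.frame(trial = t, context = ctx, cond_mi = cmi)
      }
    }
    acting <- if (agent == "meta_bayes") meta_select_model(log_ev)
              else if (agent == "meta_rl") names(q_meta)[sample_categorical(softmax(q_meta, config$beta))]
              else agent
    tr_model[t] <- acting

    if (record_kl) {
      est <- model_estimates(models[[acting]], ctx)
      truth_r <- numeric(n_cells); truth_r[goal_of[[ctx]]] <- 1
      kl_rows[[t]] <- data.frame(
        trial = t, context = ctx, trial_in_context = seen_count[[ctx]] + 1L,
        agent_model = acting,
        kl_reward = kl_to_truth(est$rhat, truth_r, "reward"),
        kl_mapping = kl_to_truth(est$phi, map_of[[ctx]], "mapping"))
    }

    loc <- sample_start(domain, ctx)
    steps <- 0L
    if (record_steps) traj <- list(loc = integer(0), action = integer(0),
                                   movement = integer(0), reward = integer(0))
    repeat {
      if (steps >= config$step_cap)
        stop(sprintf("trial %d exceeded the %d-step safety cap", t, config$step_cap))
      est <- model_estimates(models[[acting]], ctx)
      plan <- value_iteration(est$rhat, grid, pconf, v0 = warm[[acting]])
      warm[[acting]] <- plan$V
      mp <- softmax(plan$Q[loc, ], config$beta)
      ap <- primitive_action_policy(mp, est$phi)
      a <- sample_categorical(ap)
      out <- env_step(domain, ctx, loc, a)
      steps <- steps + 1L
      if (is_meta && agent == "meta_rl") {
        # prediction error needs the pre-observation point prediction
        rhat_act <- model_predict_reward(models[[acting]], ctx, out$cell)
        q_meta[acting] <- q_meta[acting] + config$eta * (out$reward - rhat_act)
      }
      models <- lapply(models, model_update, ctx = ctx, action = a,
                       movement = out$movement, cell = out$cell,
                       reward = out$reward)
      if (is_meta) {
        # model evidence scored like the clustering likelihoods: under the
        # maximum-likelihood estimate with the observation absorbed
        preds <- vapply(models, model_predict_reward, numeric(1),
                        ctx = ctx, cell = out$cell)
        log_ev <- meta_update_evidence(log_ev, out$reward, preds)
      }
      if (record_steps) {
        traj$loc <- c(traj$loc, loc); traj$action <- c(traj$action, a)
        traj$movement <- c(traj$movement, out$movement)
        traj$reward <- c(traj$reward, out$reward)
      }
      loc <- out$cell
      if (out$done) break
    }
    if (record_steps) {
      xy <- cell_to_xy(traj$loc, grid$width)
      step_rows[[t]] <- data.frame(
        trial = t, context = ctx, step = seq_len(steps),
        x = xy[, 1], y = xy[, 2], action = traj$action,
        movement = MOVEMENT_NAMES[traj$movement], reward = traj$reward,
        stringsAsFactors = FALSE)
    }
    tr_steps[t] <- steps
    seen_count[[ctx]] <- seen_count[[ctx]] + 1L
    if (is.na(goal_found[[ctx]])) goal_found[[ctx]] <- goal_of[[ctx]]
    tr_pjoint[t] <- if (agent == "meta_bayes") meta_responsibilities(log_ev)[["joint"]]
                    else if (agent == "meta_rl") softmax(q_meta, config$beta)[["joint"]]
                    else NA_real_
  }

  trials <- data.frame(trial = seq_len(n_trials), context = domain$trial_seq,
                       trial_in_context = stats::ave(seq_len(n_trials), domain$trial_seq,
                                                     FUN = seq_along),
                       steps = tr_steps, model = tr_model,
                       p_joint = tr_pjoint, stringsAsFactors = FALSE)
  mi_choice <- NULL
  if (is_meta && length(mi_rows) > 0) {
    mi_choice <- do.call(rbind, mi_rows)
    mi_choice$p_joint_end <- trials$p_joint[mi_choice$trial]
  }
  structure(list(agent = agent, seed = seed, total_steps = sum(tr_steps),
                 trials = trials,
                 kl = if (record_kl) do.call(rbind, kl_rows) else NULL,
                 steps = if (record_steps) do.call(rbind, step_rows) else NULL,
                 mi_choice = mi_choice,
                 final_models = models),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record: %s agent, %d trials, %d total steps>\n",
              x$agent, nrow(x$trials), x$total_steps))
  invisible(x)
}
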