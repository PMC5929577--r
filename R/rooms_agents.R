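# Agent loop for the diabolical rooms task. Each room is a context; the
# reward function (which corner door advances) is identical across rooms
# while the mapping changes, so an agent that clusters rewards
# independently of mappings can reuse the door immediately in new rooms,
# whereas joint clustering must re-explore whenever the mapping forces a
# new cluster, and a flat agent re-explores every room -- with every
# mistake sending it back to the start of room 1.

#' Run an agent through a diabolical rooms task
#'
#' @param spec A [make_rooms_spec()].
#' @param agent One of `"flat"`, `"independent"`, `"joint"`.
#' @param config An [agent_config()]; the rooms default discount is
#'   gamma = 0.80.
#' @param seed Integer seed for the agent's action randomness.
#' @param step_cap Total-step safety cap (diagnostic error if exceeded).
#' @return A list of class `rooms_record` with `agent`, `seed`,
#'   `total_steps`, `resets` (wrong-door events) and `room_visits` (data
#'   frame of per-visit step counts).
#' @export
run_rooms_episode <- function(spec, agent = c("independent", "joint", "flat"),
                              config = agent_config(gamma = 0.80),
                              seed = 1L, step_cap = 1000000L) {
  agent <- match.arg(agent)
  set.seed(seed)
  grid <- spec$grid
  pconf <- plan_config(config$gamma, config$beta, config$tol, config$max_iter)
  model <- model_new(agent, config$alpha, grid$n_cells, config$prune_ratio)
  warm <- numeric(grid$n_cells)
  doors_terminal <- numeric(grid$n_cells)
  doors_terminal[spec$doors] <- 1  # any door ends the room: known task structure
  ctx_of <- function(room) paste0("room", room)

  room <- 1L
  loc <- spec$start
  steps <- 0L
  resets <- 0L
  visit_room <- integer(0); visit_steps <- integer(0)
  visit_start <- 0L
  if (!model_knows_context(model, ctx_of(room)))
    model <- model_add_context(model, ctx_of(room))

  repeat {
    if (steps >= step_cap)
      stop(sprintf("rooms task exceeded the %d-step safety cap", step_cap))
    ctx <- ctx_of(room)
    est <- model_estimates(model, ctx)
    plan <- value_iteration(est$rhat, grid, pconf, v0 = warm,
                            terminal = doors_terminal)
    warm <- plan$V
    mp <- softmax(plan$Q[loc, ], config$beta)
    a <- sample_categorical(primitive_action_policy(mp, est$phi))
    out <- rooms_step(spec, room, loc, a)
    steps <- steps + 1L
    model <- model_update(model, ctx, action = a, movement = out$movement,
                          cell = out$cell, reward = out$reward)
    if (out$event != "move") {
      visit_room <- c(visit_room, room)
      visit_steps <- c(visit_steps, steps - visit_start)
      visit_start <- steps
      if (out$event == "reset") resets <- resets + 1L
    }
    if (out$task_done) break
    room <- out$room
    loc <- out$loc
    if (out$event != "move" && !model_knows_context(model, ctx_of(room)))
      model <- model_add_context(model, ctx_of(room))
  }
  structure(list(agent = agent, seed = seed, total_steps = steps,
                 resets = resets,
                 room_visits = data.frame(room = visit_room,
                                          steps = visit_steps)),
            class = "rooms_record")
}

#' @export
print.rooms_record <- function(x, ...) {
  cat(sprintf("<rooms_record: %s agent, %d steps, %d resets>\n",
              x$agent, x$total_steps, x$resets))
  invisible(x)
}
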