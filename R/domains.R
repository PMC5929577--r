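# Task domains: context-indexed grid-world MDPs. Each context is paired
# with one goal location (reward function: +1 on the goal, 0 elsewhere)
# and one action-to-movement mapping.

new_task_domain <- function(grid, mappings, goals, contexts, trials_per_context,
                            trial_seq, seed, kind) {
  structure(list(grid = grid, mappings = mappings, goals = goals,
                 contexts = contexts, trials_per_context = trials_per_context,
                 trial_seq = trial_seq, seed = seed, kind = kind),
            class = "task_domain")
}

#' @export
print.task_domain <- function(x, ...) {
  cat(sprintf("<task_domain %s: %dx%d grid, %d contexts (%d mappings x %d goals), %d trials>\n",
              x$kind, x$grid$width, x$grid$height, nrow(x$contexts),
              length(x$mappings), length(x$goals), length(x$trial_seq)))
  invisible(x)
}

#' Generate a task domain with independent reward and mapping structure
#'
#' Four contexts on a 6x6 grid form the full 2x2 cross of two goal
#' locations and two orthogonal mappings, so knowing a context's mapping
#' carries no information about its goal (and vice versa). Goals are drawn
#' uniformly at random (distinct); each context is presented four times
#' (16 trials) in a seeded random order.
#'
#' @param seed Integer seed; the same seed always yields the same domain.
#' @return A `task_domain` object with fields `grid` ([grid_spec()]),
#'   `mappings` (list of mapping vectors), `goals` (integer cell indices),
#'   `contexts` (data frame with `context_id`, `mapping_id`, `reward_id`),
#'   `trials_per_context` and `trial_seq` (context ids in trial order).
#' @export
make_sim1_domain <- function(seed) {
  seed <- as.integer(seed)
  grid <- grid_spec(6L, 6L)
  with_seed(seed, {
    goals <- sample.int(grid$n_cells, 2L)
    mappings <- make_orthogonal_mappings(2L, seed = sample.int(.Machine$integer.max, 1L))
    contexts <- data.frame(
      context_id = paste0("c", 1:4),
      mapping_id = c(1L, 1L, 2L, 2L),
      reward_id  = c(1L, 2L, 1L, 2L),
      stringsAsFactors = FALSE
    )
    trial_seq <- sample(rep(contexts$context_id, each = 4L))
    new_task_domain(grid, mappings, goals, contexts, 4L, trial_seq, seed, "sim1")
  })
}

#' Generate a task domain with dependent reward and mapping structure
#'
#' Eight contexts on a 6x6 grid pair four distinct goals with four mutually
#' orthogonal mappings such that each (goal, mapping) pair appears in
#' exactly two contexts, so the mapping deterministically predicts the goal
#' (2 bits of mutual information over contexts). Each context is presented
#' four times (32 trials) in a seeded random order.
#'
#' @inheritParams make_sim1_domain
#' @return A `task_domain`; see [make_sim1_domain()].
#' @export
make_sim2_domain <- function(seed) {
  seed <- as.integer(seed)
  grid <- grid_spec(6L, 6L)
  with_seed(seed, {
    goals <- sample.int(grid$n_cells, 4L)
    mappings <- make_orthogonal_mappings(4L, seed = sample.int(.Machine$integer.max, 1L))
    pair <- sample.int(4L)  # goal paired with each mapping
    mapping_id <- rep(1:4, 2L)
    contexts <- data.frame(
      context_id = paste0("c", 1:8),
      mapping_id = mapping_id,
      reward_id  = pair[mapping_id],
      stringsAsFactors = FALSE
    )
    trial_seq <- sample(rep(contexts$context_id, each = 4L))
    new_task_domain(grid, mappings, goals, contexts, 4L, trial_seq, seed, "sim2")
  })
}

context_row <- function(domain, context_id) {
  i <- match(context_id, domain$contexts$context_id)
  if (is.na(i)) stop("unknown context_id: ", context_id)
  domain$contexts[i, ]
}

#' Goal cell of a context
#' @param domain A `task_domain`.
#' @param context_id Context identifier.
#' @return Integer cell index of the context's goal.
#' @export
context_goal <- function(domain, context_id) {
  domain$goals[[context_row(domain, context_id)$reward_id]]
}

#' True mapping of a context
#' @inheritParams context_goal
#' @return Integer mapping vector (length 8).
#' @export
context_mapping <- function(domain, context_id) {
  domain$mappings[[context_row(domain, context_id)$mapping_id]]
}

#' Take one environment step
#'
#' Applies the context's true mapping to the chosen primitive action,
#' moves the agent with per-axis clamping at the walls (a wall bump leaves
#' the position unchanged), and reports the produced cardinal movement --
#' also on wall bumps, since the agent knows the spatial relationship
#' between states and observes the attempted displacement. Reward is 1
#' exactly when the successor cell is the context's goal, which ends the
#' trial.
#'
#' @param domain A `task_domain`.
#' @param context_id Context identifier.
#' @param cell Current cell index (1-based).
#' @param action Primitive action index in 1..8.
#' @return A list with `cell` (successor cell index), `movement`
#'   (movement index 1..4), `movement_label`, `reward` (0 or 1) and `done`.
#' @export
env_step <- function(domain, context_id, cell, action) {
  if (cell < 1L || cell > domain$grid$n_cells) stop("cell out of bounds")
  if (action < 1L || action > N_ACTIONS) stop("invalid action")
  mv <- context_mapping(domain, context_id)[[action]]
  nxt <- unname(domain$grid$succ[cell, mv])
  r <- as.integer(nxt == context_goal(domain, context_id))
  list(cell = nxt, movement = mv, movement_label = MOVEMENT_NAMES[mv],
       reward = r, done = r == 1L)
}

#' Sample a trial start location
#'
#' Uniform over all grid cells except the context's goal. Uses the global
#' RNG stream (seed the caller's RNG for reproducibility).
#'
#' @inheritParams env_step
#' @return Integer cell index.
#' @export
sample_start <- function(domain, context_id) {
  goal <- context_goal(domain, context_id)
  cells <- seq_len(domain$grid$n_cells)[-goal]
  cells[sample_categorical(rep(1, length(cells)))]
}

#' Empirical mutual information between mapping and reward assignments
#'
#' Computed over a domain's context table; 0 bits for the independent
#' (sim1) construction, 2 bits for the dependent (sim2) construction.
#'
#' @param domain A `task_domain`.
#' @return Mutual information in bits.
#' @export
domain_structure_mi <- function(domain) {
  mutual_information(as.character(domain$contexts$mapping_id),
                     as.character(domain$contexts$reward_id))
}
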