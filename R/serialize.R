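# Plain-text serialization of task specifications (YAML or JSON by file
# extension) and tidy trajectory export. Round-trips are exact: grids and
# successor tables are rebuilt from dimensions, everything else is stored.

domain_to_list <- function(domain) {
  list(kind = domain$kind, width = domain$grid$width,
       height = domain$grid$height,
       mappings = lapply(domain$mappings, unname),
       goals = as.integer(domain$goals),
       contexts = domain$contexts,
       trials_per_context = domain$trials_per_context,
       trial_seq = domain$trial_seq, seed = domain$seed)
}

list_to_domain <- function(x) {
  grid <- grid_spec(x$width, x$height)
  if (is.matrix(x$mappings))  # JSON readers simplify equal-length rows
    x$mappings <- lapply(seq_len(nrow(x$mappings)), function(i) x$mappings[i, ])
  mappings <- lapply(x$mappings, function(m) {
    m <- as.integer(unlist(m)); names(m) <- paste0("a", seq_along(m)); m
  })
  contexts <- as.data.frame(x$contexts, stringsAsFactors = FALSE)
  contexts$mapping_id <- as.integer(contexts$mapping_id)
  contexts$reward_id <- as.integer(contexts$reward_id)
  new_task_domain(grid, mappings, as.integer(x$goals), contexts,
                  as.integer(x$trials_per_context),
                  as.character(unlist(x$trial_seq)), as.integer(x$seed),
                  x$kind)
}

#' Save or load a task domain
#'
#' @param domain A `task_domain`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `load_domain` returns the `task_domain`; `save_domain` returns
#'   `path` invisibly.
#' @export
save_domain <- function(domain, path) {
  x <- domain_to_list(domain)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    x$contexts <- as.list(x$contexts)
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname save_domain
#' @export
load_domain <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  list_to_domain(x)
}

#' Save or load a rooms task specification
#'
#' @param spec A `rooms_spec`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `load_rooms_spec` returns the `rooms_spec`; `save_rooms_spec`
#'   returns `path` invisibly.
#' @export
save_rooms_spec <- function(spec, path) {
  x <- list(n_rooms = spec$n_rooms, room_size = spec$grid$width,
            mapping_order = spec$mapping_order, seed = spec$seed)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname save_rooms_spec
#' @export
load_rooms_spec <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  make_rooms_spec(n_rooms = x$n_rooms, room_size = x$room_size,
                  mapping_order = as.integer(unlist(x$mapping_order)),
                  seed = x$seed)
}

#' Export a run record's trajectory as tidy CSV
#'
#' One row per step: seed, agent, context, trial, step, x, y, action,
#' movement, reward. Requires a record produced with
#' `run_episode(..., record_steps = TRUE)`.
#'
#' @param record A `run_record` with step-level data.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory_csv <- function(record, path) {
  if (is.null(record$steps))
    stop("record has no step-level data; rerun with record_steps = TRUE")
  df <- cbind(seed = record$seed, agent = record$agent, record$steps)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a belief state to JSON
#'
#' Stores the mode, contexts, and every hypothesis's assignment, log
#' prior, log likelihood and normalized posterior (sufficient statistics
#' are summarized by cluster sizes) for checkpoint inspection.
#'
#' @param belief A `belief_state`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
belief_to_json <- function(belief, path) {
  post <- belief_posteriors(belief)
  x <- list(mode = belief$mode, alpha = belief$alpha,
            contexts = belief$contexts,
            hypotheses = lapply(seq_along(belief$hyps), function(i) {
              h <- belief$hyps[[i]]
              list(id = h$id, assignment = as.list(h$assign),
                   cluster_sizes = h$sizes, log_prior = h$lp,
                   log_likelihood = h$ll, posterior = post[i])
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
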