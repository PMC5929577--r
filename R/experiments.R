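# Reproducible experiment runners. A single master seed drives everything:
# per-domain seeds are drawn from it with a fixed splitting scheme, and
# each (domain, agent) run derives its own action seed, so results are
# bit-identical across re-runs and independent of evaluation order.

#' Experiment configuration
#'
#' @param experiment One of `"sim1"`, `"sim2"`, `"rooms"`,
#'   `"rooms_size_sweep"`, `"rooms_count_sweep"`, `"meta"`, `"mi_sweep"`,
#'   `"noise_sweep"`.
#' @param n_domains Number of seeded task domains / rooms instances
#'   (default 150).
#' @param agents Agent kinds to run (defaults depend on the experiment).
#' @param seed Master seed.
#' @param gamma,beta,alpha,eta Agent parameters; `gamma` defaults to 0.75
#'   for grid domains and 0.80 for rooms experiments.
#' @param n_rep Monte-Carlo replicates for the noise sweep.
#' @param out Optional output directory; when given, [run_experiment()]
#'   writes `results.csv`, `summary.json` and `run.log` there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("sim1", "sim2", "rooms",
                                             "rooms_size_sweep",
                                             "rooms_count_sweep", "meta",
                                             "mi_sweep", "noise_sweep"),
                              n_domains = 150L, agents = NULL, seed = 0L,
                              gamma = NULL, beta = 5.0, alpha = 1.0,
                              eta = 0.2, n_rep = 10000L, out = NULL) {
  experiment <- match.arg(experiment)
  rooms_like <- grepl("^rooms", experiment)
  if (is.null(gamma)) gamma <- if (rooms_like) 0.80 else 0.75
  if (is.null(agents)) {
    agents <- switch(experiment,
      sim1 = , sim2 = c("flat", "independent", "joint"),
      rooms = c("flat", "independent", "joint"),
      rooms_size_sweep = , rooms_count_sweep = c("independent", "joint"),
      meta = c("independent", "joint", "meta_bayes", "meta_rl"),
      mi_sweep = , noise_sweep = character(0))
  }
  structure(list(experiment = experiment, n_domains = as.integer(n_domains),
                 agents = agents, seed = as.integer(seed),
                 gamma = as.numeric(gamma), beta = as.numeric(beta),
                 alpha = as.numeric(alpha), eta = as.numeric(eta),
                 n_rep = as.integer(n_rep), out = out),
            class = "experiment_config")
}

#' Read or write an experiment configuration
#'
#' YAML or JSON is chosen by file extension; `load_config(save_config(x))`
#' round-trips exactly.
#'
#' @param config An `experiment_config`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `load_config` returns an `experiment_config`; `save_config`
#'   returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  x$agents <- as.character(unlist(x$agents))
  do.call(experiment_config, x[!vapply(x, is.null, logical(1))])
}

agent_seeds <- function(domain_seed, agents) {
  setNames(split_seed(domain_seed, length(agents)), agents)
}

#' Run a configured experiment
#'
#' Dispatches on `config$experiment`, derives all randomness from the
#' master seed, and (optionally) writes tidy CSV results, a JSON summary
#' and a parameter log to `config$out`.
#'
#' @param config An [experiment_config()].
#' @return A list with `results` (tidy data frame), `summary` (data
#'   frame from [summarize_runs()] where applicable) and `config`,
#'   invisibly when written to disk.
#' @export
run_experiment <- function(config) {
  res <- switch(config$experiment,
    sim1 = run_grid_experiment(config, make_sim1_domain),
    sim2 = run_grid_experiment(config, make_sim2_domain),
    meta = run_grid_experiment(config, make_sim1_domain),
    rooms = run_rooms_experiment(config),
    rooms_size_sweep = run_rooms_sweep(config, sizes = 3:12),
    rooms_count_sweep = run_rooms_sweep(config, counts = seq(3L, 27L, 3L)),
    mi_sweep = list(results = mi_sweep(n = 5, alpha = config$alpha), summary = NULL),
    noise_sweep = {
      r <- rbind(cbind(pair = "perfect",
                       noise_sweep(n_rep = config$n_rep, shifted = FALSE,
                                   alpha = config$alpha, seed = config$seed)),
                 cbind(pair = "shifted",
                       noise_sweep(n_rep = config$n_rep, shifted = TRUE,
                                   alpha = config$alpha, seed = config$seed + 1L)))
      list(results = r, summary = NULL)
    })
  res$config <- config
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$results, file.path(config$out, "results.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(unclass(config)), "out")],
           summary = res$summary),
      file.path(config$out, "summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("experiment: %s", config$experiment),
                 sprintf("master seed: %d", config$seed),
                 sprintf("n_domains: %d", config$n_domains),
                 sprintf("agents: %s", paste(config$agents, collapse = ", ")),
                 sprintf("gamma=%g beta=%g alpha=%g eta=%g", config$gamma,
                         config$beta, config$alpha, config$eta)),
               file.path(config$out, "run.log"))
    return(invisible(res))
  }
  res
}

run_grid_experiment <- function(config, make_domain) {
  acfg <- agent_config(gamma = config$gamma, beta = config$beta,
                       alpha = config$alpha, eta = config$eta)
  dseeds <- split_seed(config$seed, config$n_domains)
  rows <- list()
  for (i in seq_along(dseeds)) {
    dom <- make_domain(dseeds[i])
    aseeds <- agent_seeds(dseeds[i], config$agents)
    for (ag in config$agents) {
      rec <- run_episode(dom, ag, acfg, seed = aseeds[[ag]])
      rows[[length(rows) + 1L]] <- data.frame(
        domain_seed = dseeds[i], agent = ag, trial = rec$trials$trial,
        context = rec$trials$context,
        trial_in_context = rec$trials$trial_in_context,
        steps = rec$trials$steps, cum_steps = cumsum(rec$trials$steps),
        p_joint = rec$trials$p_joint, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, summary = summarize_runs(results))
}

run_rooms_experiment <- function(config) {
  acfg <- agent_config(gamma = config$gamma, beta = config$beta,
                       alpha = config$alpha, eta = config$eta)
  dseeds <- split_seed(config$seed, config$n_domains)
  rows <- list()
  for (i in seq_along(dseeds)) {
    spec <- make_rooms_spec(seed = dseeds[i])
    aseeds <- agent_seeds(dseeds[i], config$agents)
    for (ag in config$agents) {
      rec <- run_rooms_episode(spec, ag, acfg, seed = aseeds[[ag]])
      rows[[length(rows) + 1L]] <- data.frame(
        domain_seed = dseeds[i], agent = ag, steps = rec$total_steps,
        resets = rec$resets, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, summary = summarize_runs(results))
}

run_rooms_sweep <- function(config, sizes = NULL, counts = NULL) {
  acfg <- agent_config(gamma = config$gamma, beta = config$beta,
                       alpha = config$alpha, eta = config$eta)
  dseeds <- split_seed(config$seed, config$n_domains)
  grid_pts <- if (!is.null(sizes)) sizes else counts
  rows <- list()
  for (g in grid_pts) {
    for (i in seq_along(dseeds)) {
      spec <- if (!is.null(sizes))
        make_rooms_spec(n_rooms = 6L, room_size = g, seed = dseeds[i])
      else
        make_rooms_spec(n_rooms = g, room_size = 6L,
                        mapping_order = rooms_mapping_order(g), seed = dseeds[i])
      aseeds <- agent_seeds(dseeds[i] + g, config$agents)
      for (ag in config$agents) {
        rec <- run_rooms_episode(spec, ag, acfg, seed = aseeds[[ag]])
        rows[[length(rows) + 1L]] <- data.frame(
          sweep = if (!is.null(sizes)) "room_size" else "n_rooms",
          value = g, area = spec$grid$n_cells, n_rooms = spec$n_rooms,
          domain_seed = dseeds[i], agent = ag, steps = rec$total_steps,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(results = do.call(rbind, rows), summary = NULL)
}

#' Summarize per-run totals by agent
#'
#' Collapses a tidy per-trial (or per-run) results table to one row per
#' agent: number of runs, mean, standard deviation (0, flagged, when only
#' one run) and median of total steps, plus the mean steps at each
#' trial position when trial-level rows are provided.
#'
#' @param results Data frame with columns `agent`, `domain_seed`, `steps`
#'   and optionally `trial`.
#' @return Data frame with one row per agent (attribute
#'   `"trial_curves"` holds the per-trial-position means when available).
#' @export
summarize_runs <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  totals <- stats::aggregate(steps ~ agent + domain_seed, results, sum)
  sdv <- function(x) if (length(x) < 2) 0 else sd(x)
  out <- do.call(rbind, lapply(split(totals, totals$agent), function(d) {
    data.frame(agent = d$agent[1], n = nrow(d), mean_steps = mean(d$steps),
               sd_steps = sdv(d$steps), sd_defined = nrow(d) > 1,
               median_steps = median(d$steps), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if ("trial" %in% names(results)) {
    attr(out, "trial_curves") <-
      stats::aggregate(steps ~ agent + trial_in_context, results, mean)
  }
  out
}

#' Growth of rooms exploration cost with room area and room count
#'
#' Fits, per agent, an exponential growth rate of mean total steps against
#' room area (`log(steps) ~ area`) or a linear slope against the number of
#' rooms, from a [run_experiment()] rooms-sweep result.
#'
#' @param sweep_results Results data frame from a rooms sweep.
#' @return Data frame with one row per agent: `coef` (rate or slope) and
#'   the sweep kind.
#' @export
rooms_growth_rates <- function(sweep_results) {
  kind <- sweep_results$sweep[1]
  xvar <- if (kind == "room_size") "area" else "n_rooms"
  means <- stats::aggregate(steps ~ agent + get(xvar), sweep_results, mean)
  names(means)[2] <- "x"
  do.call(rbind, lapply(split(means, means$agent), function(d) {
    cf <- if (kind == "room_size") stats::coef(stats::lm(log(steps) ~ x, d))[2]
          else stats::coef(stats::lm(steps ~ x, d))[2]
    data.frame(agent = d$agent[1], sweep = kind, coef = unname(cf),
               stringsAsFactors = FALSE)
  }))
}
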