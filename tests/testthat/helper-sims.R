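# Shared simulation runs, computed once per test session. The acceptance
# checks average over 40 seeded domains (standard errors of a few steps
# against tolerance bands of 20+ steps); property checks reuse the same
# runs where possible.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

ALL_AGENTS <- c("independent", "joint", "flat", "meta_bayes", "meta_rl")

grid_sim_totals <- function(kind, n = 40, master = 2024,
                            agents = ALL_AGENTS) {
  cached(paste(kind, n, master, paste(agents, collapse = ",")), {
    make_dom <- if (kind == "sim1") make_sim1_domain else make_sim2_domain
    seeds <- split_seed(master, n)
    rows <- lapply(seeds, function(s) {
      dom <- make_dom(s)
      aseeds <- setNames(split_seed(s, length(ALL_AGENTS)), ALL_AGENTS)
      recs <- lapply(agents, function(a)
        run_episode(dom, a, seed = aseeds[[a]]))
      data.frame(domain_seed = s, agent = agents,
                 total = vapply(recs, function(r) r$total_steps, numeric(1)),
                 p_joint_first = vapply(recs, function(r)
                   mean(head(r$trials$p_joint, nrow(r$trials) %/% 4)), numeric(1)),
                 p_joint_last = vapply(recs, function(r)
                   mean(tail(r$trials$p_joint, nrow(r$trials) %/% 4)), numeric(1)))
    })
    do.call(rbind, rows)
  })
}

rooms_totals <- function(n = 40, master = 512) {
  cached(paste("rooms", n, master), {
    seeds <- split_seed(master, n)
    agents <- c("flat", "independent", "joint")
    cfg <- agent_config(gamma = 0.80)
    rows <- lapply(seeds, function(s) {
      spec <- make_rooms_spec(seed = s)
      aseeds <- setNames(split_seed(s, 3), agents)
      data.frame(domain_seed = s, agent = agents,
                 total = vapply(agents, function(a)
                   run_rooms_episode(spec, a, cfg, seed = aseeds[[a]])$total_steps,
                   numeric(1)))
    })
    do.call(rbind, rows)
  })
}

agent_means <- function(df) {
  with(df, tapply(total, agent, mean))
}

paired_less <- function(df, a, b) {
  # one-sided paired test that agent a takes fewer steps than agent b
  xa <- df$total[df$agent == a][order(df$domain_seed[df$agent == a])]
  xb <- df$total[df$agent == b][order(df$domain_seed[df$agent == b])]
  stats::t.test(xa, xb, paired = TRUE, alternative = "less")$p.value
}
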