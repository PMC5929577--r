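# Independent oracles used by the tests. These re-derive quantities by
# brute force or closed form, without touching the package's incremental
# code paths.

# All set partitions of n elements (list of integer label vectors with
# clusters numbered in order of first appearance).
enumerate_partitions <- function(n) {
  parts <- list(integer(0))
  for (i in seq_len(n)) {
    nxt <- list()
    for (p in parts) {
      k <- if (length(p) == 0) 0L else max(p)
      for (j in seq_len(k + 1L)) nxt[[length(nxt) + 1L]] <- c(p, j)
    }
    parts <- nxt
  }
  parts
}

# Exchangeable CRP partition probability (EPPF), unnormalized over all
# partitions of the same n.
crp_partition_prob <- function(labels, alpha) {
  sizes <- tabulate(labels)
  num <- alpha^length(sizes) * prod(factorial(sizes - 1))
  den <- prod(seq(0, length(labels) - 1) + alpha)
  num / den
}

# Plug-in ML log likelihood of an observation stream under a fixed
# partition, replicating the scoring convention from first principles:
# counts absorb each observation before it is scored.
# obs: data frame with columns ctx, type ("map"/"rew"), a, mv, cell, r.
oracle_partition_loglik <- function(labels, ctx_ids, obs, n_cells = 36,
                                    eps = 0.01, s0 = 0.01, floor = 1e-6) {
  cl_of <- setNames(labels, ctx_ids)
  ll <- 0
  stats <- list()
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, ]
    k <- as.character(cl_of[[o$ctx]])
    if (is.null(stats[[k]]))
      stats[[k]] <- list(map = matrix(0, 8, 4), s = rep(s0, n_cells),
                         f = rep(0, n_cells))
    st <- stats[[k]]
    if (o$type == "map") {
      st$map[o$a, o$mv] <- st$map[o$a, o$mv] + 1
      p <- (st$map[o$a, o$mv] + eps) / (sum(st$map[o$a, ]) + 4 * eps)
      ll <- ll + log(p)
    } else {
      st$s[o$cell] <- st$s[o$cell] + o$r
      st$f[o$cell] <- st$f[o$cell] + (1 - o$r)
      phat <- st$s[o$cell] / (st$s[o$cell] + st$f[o$cell])
      pr <- if (o$r == 1) phat else 1 - phat
      ll <- ll + log(max(pr, floor))
    }
    stats[[k]] <- st
  }
  ll
}

# Exhaustive posterior over partitions given an observation stream.
oracle_partition_posterior <- function(ctx_ids, obs, alpha = 1,
                                       n_cells = 36) {
  parts <- enumerate_partitions(length(ctx_ids))
  logw <- vapply(parts, function(p) {
    log(crp_partition_prob(p, alpha)) +
      oracle_partition_loglik(p, ctx_ids, obs, n_cells)
  }, numeric(1))
  w <- exp(logw - max(logw))
  names(w) <- vapply(parts, paste, character(1), collapse = "")
  w / sum(w)
}

# Canonical partition key of a belief hypothesis (clusters renumbered in
# order of first appearance over ctx_ids).
partition_key <- function(assign, ctx_ids) {
  lab <- assign[ctx_ids]
  paste(as.integer(factor(lab, levels = unique(lab))), collapse = "")
}

# Posterior over canonical partitions held by a belief state.
belief_partition_posterior <- function(belief, ctx_ids) {
  w <- belief_posteriors(belief)
  keys <- vapply(belief$hyps, function(h) partition_key(h$assign, ctx_ids),
                 character(1))
  p <- tapply(w, keys, sum)
  setNames(as.numeric(p), dimnames(p)[[1]])
}

# Shortest-path length between cells on an open grid (no obstacles):
# Manhattan distance, cross-checked by breadth-first search.
bfs_distance <- function(grid, from, to) {
  dist <- rep(NA_integer_, grid$n_cells)
  dist[from] <- 0L
  frontier <- from
  while (is.na(dist[to])) {
    nxt <- setdiff(unique(as.vector(grid$succ[frontier, ])),
                   which(!is.na(dist)))
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  dist[to]
}

# Same partition up to cluster relabeling?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
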