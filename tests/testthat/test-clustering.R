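test_that("the CRP assignment prior follows cluster popularity", {
  expect_equal(crp_assignment_prior(c(2), 1, 1), 2 / 3)
  expect_equal(crp_assignment_prior(c(2), 1, 2), 1 / 3)
  expect_equal(crp_assignment_prior(integer(0), 1, 1), 1)  # first context
  expect_gt(crp_assignment_prior(c(3, 1), 1e9, 3), 1 - 1e-8)  # flat limit
  # normalization over all options
  p <- vapply(1:4, function(k) crp_assignment_prior(c(2, 1, 1), 0.7, k), numeric(1))
  expect_equal(sum(p), 1)
  expect_error(crp_assignment_prior(c(2), 1, 5))
})

test_that("augmentation spawns one child per cluster plus a new one", {
  b <- new_belief("mapping", alpha = 1, prune_ratio = 0)
  b <- augment_on_new_context(b, "c1")
  expect_equal(length(b$hyps), 1)
  b <- augment_on_new_context(b, "c2")
  expect_equal(length(b$hyps), 2)        # Bell(2)
  b <- augment_on_new_context(b, "c3")
  expect_equal(length(b$hyps), 5)        # Bell(3)
  expect_error(augment_on_new_context(b, "c3"))

  # a single hypothesis with 2 clusters spawns 3 children
  b2 <- new_belief("mapping", prune_ratio = 0)
  b2 <- augment_on_new_context(b2, "x")
  b2 <- augment_on_new_context(b2, "y")
  two_cluster <- Filter(function(h) length(h$sizes) == 2, b2$hyps)
  b2$hyps <- two_cluster
  b2 <- augment_on_new_context(b2, "z")
  expect_equal(length(b2$hyps), 3)

  # flat mode: exactly one hypothesis, each context its own cluster
  f <- new_belief("flat")
  for (cc in c("c1", "c2", "c3")) f <- augment_on_new_context(f, cc)
  expect_equal(length(f$hyps), 1)
  expect_equal(unname(f$hyps[[1]]$assign), 1:3)
})

test_that("popularity bias: with no data, prior mass on a cluster tracks its size", {
  b <- new_belief("mapping", alpha = 1, prune_ratio = 0)
  for (cc in c("c1", "c2", "c3")) {
    b <- augment_on_new_context(b, cc)
    b <- update_likelihood(b, cc, action = 1, movement = 1)  # identical data
  }
  # force the all-in-one-cluster hypothesis, then add a context
  b$hyps <- Filter(function(h) length(h$sizes) == 1, b$hyps)
  b <- augment_on_new_context(b, "c4")
  post <- belief_posteriors(b)
  joins <- vapply(b$hyps, function(h) h$assign[["c4"]] == 1, logical(1))
  # prior mass on joining the size-3 cluster is 3x the new-cluster mass
  expect_equal(sum(post[joins]) / sum(post[!joins]), 3, tolerance = 1e-10)
})

test_that("shared clusters pool observation counts; separate clusters do not", {
  b <- new_belief("mapping", prune_ratio = 0)
  b <- augment_on_new_context(b, "c1")
  b <- augment_on_new_context(b, "c2")
  b <- update_likelihood(b, "c1", action = 1, movement = 2)
  b <- update_likelihood(b, "c2", action = 1, movement = 2)
  merged <- Filter(function(h) length(h$sizes) == 1, b$hyps)[[1]]
  split <- Filter(function(h) length(h$sizes) == 2, b$hyps)[[1]]
  expect_equal(merged$clusters[[1]]$map[1, 2], 2)
  expect_equal(split$clusters[[1]]$map[1, 2], 1)
  expect_equal(split$clusters[[2]]$map[1, 2], 1)
})

test_that("update types must be consistent with the belief mode", {
  b <- augment_on_new_context(new_belief("mapping"), "c1")
  expect_error(update_likelihood(b, "c1", cell = 3, reward = 0))
  r <- augment_on_new_context(new_belief("reward"), "c1")
  expect_error(update_likelihood(r, "c1", action = 1, movement = 1))
})

test_that("MAP extraction returns the highest-posterior hypothesis, earliest on ties", {
  b <- new_belief("mapping", prune_ratio = 0)
  b <- augment_on_new_context(b, "c1")
  expect_equal(map_hypothesis(b)$id, b$hyps[[1]]$id)
  b <- augment_on_new_context(b, "c2")
  # the two partitions of 2 contexts have priors 1/2 each: a tie
  expect_equal(belief_posteriors(b), c(0.5, 0.5))
  expect_equal(map_hypothesis(b)$id, min(vapply(b$hyps, `[[`, integer(1), "id")))
  expect_error(map_hypothesis(new_belief("joint")))
})

test_that("posteriors over partitions match exhaustive enumeration", {
  set.seed(42)
  ctx_ids <- c("c1", "c2", "c3")
  # a small stream mixing mapping and reward events, two contexts agreeing
  obs <- data.frame(
    ctx = c("c1", "c1", "c2", "c2", "c3", "c3", "c1", "c3"),
    type = c("map", "rew", "map", "rew", "map", "rew", "map", "map"),
    a = c(1, NA, 1, NA, 1, NA, 3, 3),
    mv = c(2, NA, 2, NA, 4, NA, 1, 1),
    cell = c(NA, 5, NA, 5, NA, 9, NA, NA),
    r = c(NA, 1, NA, 1, NA, 0, NA, NA),
    stringsAsFactors = FALSE
  )
  for (mode in c("mapping", "reward", "joint")) {
    use <- switch(mode, mapping = obs[obs$type == "map", ],
                  reward = obs[obs$type == "rew", ], obs)
    b <- new_belief(mode, alpha = 1, n_cells = 36, prune_ratio = 0)
    for (cc in ctx_ids) b <- augment_on_new_context(b, cc)
    for (i in seq_len(nrow(use))) {
      o <- use[i, ]
      b <- if (o$type == "map")
        update_likelihood(b, o$ctx, action = o$a, movement = o$mv)
      else
        update_likelihood(b, o$ctx, cell = o$cell, reward = o$r)
    }
    got <- belief_partition_posterior(b, ctx_ids)
    want <- oracle_partition_posterior(ctx_ids, use)
    # oracle scores only the events the mode tracks
    expect_equal(length(got), 5L)  # Bell(3)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("the partition posterior is invariant to context presentation order", {
  ctx_sets <- list(c("c1", "c2", "c3"), c("c3", "c1", "c2"), c("c2", "c3", "c1"))
  per_ctx <- list(
    c1 = list(list(a = 1, mv = 2), list(a = 2, mv = 3)),
    c2 = list(list(a = 1, mv = 2), list(a = 2, mv = 3)),
    c3 = list(list(a = 1, mv = 4), list(a = 2, mv = 1))
  )
  posts <- lapply(ctx_sets, function(order) {
    b <- new_belief("mapping", alpha = 1, prune_ratio = 0)
    for (cc in order) {
      b <- augment_on_new_context(b, cc)
      for (o in per_ctx[[cc]])
        b <- update_likelihood(b, cc, action = o$a, movement = o$mv)
    }
    p <- belief_partition_posterior(b, c("c1", "c2", "c3"))
    p[order(names(p))]
  })
  expect_equal(posts[[1]], posts[[2]], tolerance = 1e-10)
  expect_equal(posts[[1]], posts[[3]], tolerance = 1e-10)
})

test_that("pruning keeps hypotheses within the ratio of the MAP and renormalizes", {
  b <- new_belief("mapping", alpha = 1, prune_ratio = 0.1)
  for (cc in paste0("c", 1:3)) {
    b <- augment_on_new_context(b, cc)
    for (i in 1:6) b <- update_likelihood(b, cc, action = i, movement = (i %% 4) + 1)
  }
  lpost <- vapply(b$hyps, function(h) h$lp + h$ll, numeric(1))
  expect_true(all(lpost >= max(lpost) + log(0.1) - 1e-12))
  expect_equal(sum(belief_posteriors(b)), 1)
})

test_that("the first mapping observation in a fresh cluster is worth exactly 2 bits", {
  fresh <- matrix(0, 8, 4)
  expect_equal(mapping_observation_bits(fresh, 1, 3), 2)
  seen <- fresh; seen[1, 3] <- 5
  expect_lt(mapping_observation_bits(seen, 1, 3), 0.1)
})

test_that("belief states serialize to inspectable JSON", {
  b <- new_belief("joint", prune_ratio = 0)
  b <- augment_on_new_context(b, "c1")
  b <- update_likelihood(b, "c1", action = 1, movement = 1, cell = 2, reward = 0)
  path <- tempfile(fileext = ".json")
  belief_to_json(b, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$mode, "joint")
  expect_equal(x$contexts, "c1")
  expect_equal(x$hypotheses$posterior, 1)
})
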