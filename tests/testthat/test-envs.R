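test_that("cardinal movements and grid successor tables are consistent", {
  mv <- cardinal_movements()
  expect_equal(rownames(mv), c("North", "South", "East", "West"))
  expect_equal(unname(mv["North", ]), c(0L, 1L))
  expect_equal(unname(mv["South", ]), c(0L, -1L))
  expect_equal(unname(mv["East", ]), c(1L, 0L))
  expect_equal(unname(mv["West", ]), c(-1L, 0L))

  g <- grid_spec(6, 6)
  # closure: every successor in bounds, displacement per axis in {-1,0,1}
  expect_true(all(g$succ >= 1 & g$succ <= g$n_cells))
  for (j in 1:4) {
    d <- cell_to_xy(g$succ[, j], 6) - cell_to_xy(seq_len(36), 6)
    expect_true(all(abs(d) <= 1))
  }
  expect_error(grid_spec(1, 6))
})

test_that("orthogonal mapping sets are balanced and pairwise disagree everywhere", {
  for (seed in 1:20) {
    maps <- make_orthogonal_mappings(4, seed)
    for (m in maps) expect_true(compclust:::mapping_balanced(m))
    for (i in 1:3) for (j in (i + 1):4)
      expect_true(mappings_orthogonal(maps[[i]], maps[[j]]))
  }
  expect_identical(make_orthogonal_mappings(3, 7), make_orthogonal_mappings(3, 7))
})

test_that("sim1 domains cross two goals with two mappings independently", {
  for (seed in c(0, 1, 17)) {
    dom <- make_sim1_domain(seed)
    expect_equal(nrow(dom$contexts), 4)
    expect_equal(length(unique(dom$goals)), 2)
    combos <- paste(dom$contexts$mapping_id, dom$contexts$reward_id)
    expect_equal(sort(combos), c("1 1", "1 2", "2 1", "2 2"))
    expect_equal(domain_structure_mi(dom), 0)
    expect_equal(as.vector(table(dom$trial_seq)), rep(4L, 4))
  }
  expect_identical(make_sim1_domain(0), make_sim1_domain(0))
  expect_false(identical(make_sim1_domain(0), make_sim1_domain(1)))
})

test_that("sim2 domains make the mapping fully predictive of the goal", {
  for (seed in c(0, 3)) {
    dom <- make_sim2_domain(seed)
    expect_equal(nrow(dom$contexts), 8)
    expect_equal(length(unique(dom$goals)), 4)
    expect_equal(domain_structure_mi(dom), 2)  # 2 bits
    pairs <- table(paste(dom$contexts$mapping_id, dom$contexts$reward_id))
    expect_true(all(pairs == 2))
    for (i in 1:3) for (j in (i + 1):4)
      expect_true(mappings_orthogonal(dom$mappings[[i]], dom$mappings[[j]]))
  }
  expect_identical(make_sim2_domain(5), make_sim2_domain(5))
})

test_that("environment steps clamp at walls and terminate on the goal", {
  dom <- make_sim1_domain(2)
  ctx <- dom$contexts$context_id[1]
  m <- context_mapping(dom, ctx)
  west_action <- which(m == 4)[1]
  out <- env_step(dom, ctx, xy_to_cell(0, 0, 6), west_action)
  expect_equal(out$cell, xy_to_cell(0, 0, 6))  # wall bump: no move
  expect_equal(out$movement_label, "West")     # movement still observed
  expect_equal(out$reward, 0)

  goal <- context_goal(dom, ctx)
  gxy <- cell_to_xy(goal, 6)
  if (gxy[2] > 0) {
    below <- xy_to_cell(gxy[1], gxy[2] - 1, 6)
    north_action <- which(m == 1)[1]
    out <- env_step(dom, ctx, below, north_action)
    expect_equal(out$reward, 1)
    expect_true(out$done)
  }
  expect_error(env_step(dom, "nope", 1, 1))
  expect_error(env_step(dom, ctx, 99, 1))
})

test_that("greedy trials under the true model take exactly the shortest path", {
  dom <- make_sim1_domain(11)
  set.seed(1)
  for (rep in 1:20) {
    ctx <- sample(dom$contexts$context_id, 1)
    goal <- context_goal(dom, ctx)
    m <- context_mapping(dom, ctx)
    loc <- sample_start(dom, ctx)
    d_oracle <- bfs_distance(dom$grid, loc, goal)
    expect_equal(d_oracle, manhattan(loc, goal, 6)[1])
    steps <- 0
    while (TRUE) {
      xy <- cell_to_xy(loc, 6); gxy <- cell_to_xy(goal, 6)
      mv <- if (gxy[1] > xy[1]) 3 else if (gxy[1] < xy[1]) 4
            else if (gxy[2] > xy[2]) 1 else 2
      out <- env_step(dom, ctx, loc, which(m == mv)[1])
      steps <- steps + 1
      loc <- out$cell
      if (out$done) break
    }
    expect_equal(steps, d_oracle)
  }
})

test_that("start locations are uniform over non-goal cells", {
  dom <- make_sim1_domain(4)
  ctx <- dom$contexts$context_id[1]
  goal <- context_goal(dom, ctx)
  set.seed(99)
  draws <- vapply(seq_len(1e5), function(i) sample_start(dom, ctx), integer(1))
  expect_false(goal %in% draws)
  counts <- tabulate(draws, nbins = 36)[-goal]
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  # seeded reproducibility
  set.seed(5); a <- replicate(10, sample_start(dom, ctx))
  set.seed(5); b <- replicate(10, sample_start(dom, ctx))
  expect_identical(a, b)
})

test_that("rooms specifications follow the corner-door layout and block orders", {
  expect_equal(rooms_mapping_order(6), c(1, 1, 2, 2, 3, 3))
  expect_equal(rooms_mapping_order(9), rep(1:3, each = 3))
  expect_error(rooms_mapping_order(7))

  spec <- make_rooms_spec(n_rooms = 6, room_size = 3, seed = 1)
  xy <- cell_to_xy(spec$doors, 3)
  expect_setequal(paste(xy[, 1], xy[, 2]), c("0 2", "2 2", "2 0"))  # NW NE SE
  expect_equal(spec$start, xy_to_cell(0, 0, 3))
  expect_false(spec$start %in% spec$doors)
  expect_error(make_rooms_spec(room_size = 2))
})

test_that("rooms steps advance, reset, and complete per the door semantics", {
  spec <- make_rooms_spec(seed = 3)
  m1 <- spec$mappings[[spec$mapping_order[1]]]
  # from the cell below the NE door, a North movement enters the correct door
  below_ne <- xy_to_cell(5, 4, 6)
  out <- rooms_step(spec, 1, below_ne, which(m1 == 1)[1])
  expect_equal(out$event, "advance")
  expect_equal(out$reward, 1)
  expect_equal(out$room, 2)
  expect_equal(out$loc, spec$start)
  # wrong door (SE) resets to room 1 from any room
  m4 <- spec$mappings[[spec$mapping_order[4]]]
  beside_se <- xy_to_cell(4, 0, 6)
  out <- rooms_step(spec, 4, beside_se, which(m4 == 3)[1])
  expect_equal(out$event, "reset")
  expect_equal(out$reward, 0)
  expect_equal(out$room, 1)
  expect_equal(out$loc, spec$start)
  # correct door in the last room completes the task
  m6 <- spec$mappings[[spec$mapping_order[6]]]
  out <- rooms_step(spec, 6, below_ne, which(m6 == 1)[1])
  expect_true(out$task_done)
  expect_error(rooms_step(spec, 7, 1, 1))
})

test_that("the known-correct rooms policy costs the summed door distances", {
  spec <- make_rooms_spec(seed = 8)
  per_room <- manhattan(spec$start, spec$correct_door, 6)[1]
  room <- 1; loc <- spec$start; steps <- 0
  repeat {
    m <- spec$mappings[[spec$mapping_order[room]]]
    xy <- cell_to_xy(loc, 6)
    # shortest path that avoids the NW and SE wrong-door corners:
    # rise to the penultimate row, cross East, then enter the NE door
    mv <- if (xy[2] < 4) 1 else if (xy[1] < 5) 3 else 1
    out <- rooms_step(spec, room, loc, which(m == mv)[1])
    steps <- steps + 1
    if (out$task_done) break
    room <- out$room; loc <- out$loc
  }
  expect_equal(steps, spec$n_rooms * per_room)
})

test_that("domain and rooms specifications round-trip through YAML and JSON", {
  dom <- make_sim2_domain(9)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    save_domain(dom, path)
    expect_identical(load_domain(path), dom)
  }
  spec <- make_rooms_spec(n_rooms = 9, room_size = 4,
                          mapping_order = rooms_mapping_order(9), seed = 2)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    save_rooms_spec(spec, path)
    expect_identical(load_rooms_spec(path), spec)
  }
})
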