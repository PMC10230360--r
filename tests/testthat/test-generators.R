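test_that("generated items honour the tolerance contract across games", {
  set.seed(31)
  cases <- list(
    list(game = "assembly", band = target_band("assembly")),
    list(game = "spatial_memory", band = target_band("spatial_memory")),
    list(game = "sequence_memory", band = target_band("sequence_memory")),
    list(game = "path_tracking", band = target_band("path_tracking")),
    list(game = "maze", band = target_band("maze"))
  )
  for (case in cases) {
    for (i in 1:20) {
      cd <- runif(1, case$band[1], case$band[2])
      gen <- generate_item(case$game, generator_config(cd))
      expect_lte(abs(gen$breakdown$c_play - cd), 0.25,
                 label = sprintf("%s target %.2f", case$game, cd))
      expect_equal(gen$breakdown$c_play, play_complexity(gen$item)$c_play)
    }
  }
})

test_that("a huge tolerance accepts the first random item", {
  set.seed(8)
  gen <- generate_item("assembly", generator_config(20, tol = 1e6))
  expect_equal(gen$iterations, 1L)
})

test_that("the minimum 2x2 Assembly target is met by an all-identical item", {
  # exhaustive minimum over 2x2 grids on a reduced alphabet {square, strip,
  # triangle of colour A}
  alphabet <- c(1L, 3L, 7L)
  combos <- expand.grid(a = alphabet, b = alphabet, c = alphabet, d = alphabet)
  cp <- apply(combos, 1, function(v) {
    play_complexity(grid_item(matrix(as.integer(v), 2, 2), "assembly"))$c_play
  })
  cmin_idx <- which.min(cp)
  expect_equal(length(unique(as.integer(combos[cmin_idx, ]))), 1L)
  # the global minimum over all shapes is the uniform colour-A square grid
  cmin <- play_complexity(grid_item(matrix(1L, 2, 2), "assembly"))$c_play
  set.seed(91)
  gen <- generate_item("assembly", generator_config(cmin, size = 2))
  expect_equal(gen$breakdown$c_config, 0)
  expect_equal(length(unique(as.vector(gen$item$cells))), 1L)
})

test_that("infeasible targets raise a condition carrying the best item", {
  set.seed(12)
  err <- tryCatch(
    generate_item("assembly", generator_config(1000, max_iterations = 300)),
    cubecat_infeasible = function(e) e
  )
  expect_s3_class(err, "cubecat_infeasible")
  expect_s3_class(err$best_item, "grid_item")
  expect_s3_class(err$best_breakdown, "complexity_breakdown")
})

test_that("generation is reproducible from the seed", {
  a <- generate_item("maze", generator_config(18, seed = 99))
  b <- generate_item("maze", generator_config(18, seed = 99))
  expect_identical(a, b)
  s1 <- generate_item("sequence_memory", generator_config(12, seed = 5))
  s2 <- generate_item("sequence_memory", generator_config(12, seed = 5))
  expect_identical(s1$item$shapes, s2$item$shapes)
})

test_that("mutation changes exactly one feature", {
  set.seed(17)
  g <- random_item <- generate_item("assembly", generator_config(25))$item
  harder <- mutate_item(g, "harder")
  expect_equal(sum(harder$cells != g$cells), 1L)  # Hamming distance 1
  expect_gt(play_complexity(harder)$c_play, play_complexity(g)$c_play)
  easier <- mutate_item(g, "easier")
  expect_lt(play_complexity(easier)$c_play, play_complexity(g)$c_play)
  # maze mutation moves the end point and leaves the walls alone
  mz <- generate_item("maze", generator_config(18))$item
  mut <- cubecat:::propose_maze_end(mz)
  expect_identical(mut$open_right, mz$open_right)
  expect_identical(mut$open_down, mz$open_down)
  expect_identical(mut$start, mz$start)
  expect_false(all(mut$end == mz$end))
  # an easier mutation exists from the maximal-complexity 2x2 item on the
  # reduced alphabet (established by full enumeration)
  alphabet <- c(1L, 3L, 7L)
  combos <- expand.grid(a = alphabet, b = alphabet, c = alphabet, d = alphabet)
  cp <- apply(combos, 1, function(v) {
    play_complexity(grid_item(matrix(as.integer(v), 2, 2), "assembly"))$c_play
  })
  top <- grid_item(matrix(as.integer(combos[which.max(cp), ]), 2, 2), "assembly")
  eas <- mutate_item(top, "easier")
  expect_lt(play_complexity(eas)$c_play, max(cp))
})

test_that("perfect mazes have the spanning-tree wall count and are solvable", {
  set.seed(55)
  for (d in c(3L, 5L, 8L)) {
    mz <- generate_maze(d)
    n_open <- sum(mz$open_right[, -d]) + sum(mz$open_down[-d, ])
    expect_equal(n_open, d^2 - 1L)
    expect_no_error(astar_shortest(mz))
  }
  # determinism under a fixed seed
  set.seed(1); m1 <- generate_maze(6)
  set.seed(1); m2 <- generate_maze(6)
  expect_identical(m1, m2)
})

test_that("generated paths are valid self-avoiding walks of the asked size", {
  set.seed(66)
  for (v in c(2L, 7L, 14L, 25L)) {
    p <- generate_path(v)
    expect_equal(p$V, v)
    # independent adjacency recount
    steps <- abs(diff(p$nodes[, 1])) + abs(diff(p$nodes[, 2]))
    expect_true(all(steps == 1L))
    expect_equal(anyDuplicated(paste(p$nodes[, 1], p$nodes[, 2])), 0L)
    expect_equal(p$degrees, c(1L, rep(2L, v - 2L), 1L))
  }
  expect_equal(generate_path(2)$V, 2L)
})

test_that("shape-matching pool levels are deterministic in complexity", {
  pool <- shape_matching_pool()
  expect_equal(nrow(pool), 10L)
  expect_equal(pool$c_play, sort(pool$c_play))  # ladder ordered by difficulty
  # easiest level: identical shapes, zero complexity
  set.seed(2)
  easiest <- generate_shape_matching(1)
  expect_equal(length(unique(as.vector(easiest$base$cells))), 1L)
  expect_equal(play_complexity(easiest)$c_play, 0)
  # two draws at one level: different items, equal complexity
  for (lvl in c(2L, 7L, 10L)) {
    draws <- replicate(6, generate_shape_matching(lvl), simplify = FALSE)
    cps <- vapply(draws, function(d) play_complexity(d)$c_play, numeric(1))
    expect_equal(max(cps) - min(cps), 0, info = paste("level", lvl))
    expect_equal(unique(cps), pool$c_play[lvl])
  }
  # the answer always equals the hidden cell
  it <- generate_shape_matching(5)
  expect_equal(it$answer,
               it$base$cells[it$missing_cell[1] + 1, it$missing_cell[2] + 1])
  expect_error(generate_shape_matching(99), "invalid")
})

test_that("the shape-matching generator snaps to the nearest pool level", {
  pool <- shape_matching_pool()
  set.seed(3)
  gen <- generate_item("shape_matching", generator_config(pool$c_play[8] + 0.1))
  expect_equal(gen$breakdown$c_play, pool$c_play[8])
  expect_error(generate_item("shape_matching", generator_config(50)),
               class = "cubecat_infeasible")
})
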