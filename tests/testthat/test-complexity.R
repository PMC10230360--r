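test_that("shannon entropy matches the closed forms", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)       # uniform: log2(n)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)          # point mass
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.7, 0.2)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "nonnegative")
})

test_that("compositional complexity is the information of the shape multiset", {
  # four colour-A squares: 4 * log2(6 * 1)
  squares <- grid_item(matrix(1L, 2, 2), "assembly")
  expect_equal(compositional_complexity(squares), 4 * log2(6),
               tolerance = 1e-12)
  expect_equal(4 * log2(6), 10.339850002884624)
  # arrangement-invariance: any permutation of the same multiset is equal
  ids <- c(1L, 4L, 7L, 12L, 7L, 4L, 1L, 12L, 9L)
  vals <- replicate(5, {
    compositional_complexity(grid_item(matrix(sample(ids), 3, 3), "assembly"))
  })
  expect_true(all(abs(vals - vals[1]) < 1e-12))
  # empty composition scores zero
  expect_equal(compositional_complexity(integer()), 0)
})

test_that("pair extraction yields the ordered circulant pairs", {
  # a row (3, 5, 4) read at 0 degrees closes into (3,5), (5,4), (4,3)
  pr <- extract_pairs(matrix(c(3L, 5L, 4L), 1, 3), "0", circulant = TRUE)
  expect_equal(unname(pr), rbind(c(3L, 5L), c(5L, 4L), c(4L, 3L)))
  # a single cell has no pairs in any direction
  for (d in c("0", "45", "90", "135")) {
    expect_equal(nrow(extract_pairs(matrix(7L, 1, 1), d)), 0L)
  }
  # all-same 3x3 grid: every pair identical, counts match the brute-force scan
  m <- matrix(2L, 3, 3)
  for (d in c("0", "45", "90", "135")) {
    pr <- extract_pairs(m, d)
    expect_true(all(pr == 2L))
    expect_equal(nrow(pr), nrow(oracle_pairs(m, d)), info = d)
  }
})

test_that("co-occurrence counting matches an independent dictionary oracle", {
  # two (1,5) pairs land as a 2 in the (1,5) coordinate
  m <- matrix(c(1L, 1L, 5L, 5L), 2, 2)
  f <- build_cooccurrence(m, "0", circulant = TRUE)
  expect_equal(f[1, 5], 2L)
  expect_equal(f[5, 1], 2L)
  expect_equal(sum(f), nrow(extract_pairs(m, "0")))
  # empty pair list gives the zero matrix
  expect_equal(sum(build_cooccurrence(matrix(3L, 1, 1), "0")), 0L)
  # random grids against the oracle, all direction subsets
  set.seed(101)
  for (rep in 1:25) {
    dim <- sample(2:3, 1)
    m <- matrix(sample.int(14L, dim * dim, replace = TRUE), dim, dim)
    dirs <- sample(c("0", "45", "90", "135"), sample(1:4, 1))
    expect_equal(unclass(build_cooccurrence(m, dirs))[,],
                 oracle_cooccurrence(m, dirs),
                 ignore_attr = TRUE)
  }
})

test_that("pair weights follow the colour-and-orientation rule", {
  tax <- surface_shapes()
  # different colour AND different orientation: weight 2
  expect_equal(pair_weight(3L, 6L), 2L)   # strip A 0 vs strip B 1
  expect_equal(pair_weight(1L, 12L), 2L)  # square A 0 vs triangle B 1
  # identical shapes: weight 1
  expect_equal(pair_weight(9L, 9L), 1L)
  # different colour, same orientation: weight 1
  expect_equal(pair_weight(3L, 5L), 1L)
  # same colour, different orientation: weight 1
  expect_equal(pair_weight(7L, 8L), 1L)
  # the full matrix agrees with elementwise evaluation
  W <- shape_pair_weights()
  for (i in c(1L, 4L, 11L)) for (j in c(2L, 6L, 14L)) {
    expect_equal(W[i, j], pair_weight(i, j))
  }
})

test_that("weighted entropy composes probabilities and weights", {
  n <- 14L
  f <- matrix(0L, n, n); w <- matrix(1, n, n)
  f[2, 3] <- 7L
  expect_equal(weighted_entropy(f, w), 0)        # single cell: p = 1
  f[5, 5] <- 7L
  expect_equal(weighted_entropy(f, w), 1)        # two equal cells, unit weights
  expect_equal(weighted_entropy(f, 2 * w), 2)    # linear in the weights
  expect_warning(val <- weighted_entropy(matrix(0L, n, n), w), "all-zero")
  expect_equal(val, 0)
})

test_that("configurational complexity separates arrangements of one multiset", {
  # orderly (blocked) vs interleaved arrangement of the same shapes
  ids <- c(3L, 3L, 3L, 6L, 6L, 6L, 9L, 9L, 9L)
  a <- grid_item(matrix(ids, 3, 3), "assembly")
  b <- grid_item(matrix(ids[c(1, 4, 7, 2, 5, 8, 3, 6, 9)], 3, 3), "assembly")
  expect_equal(compositional_complexity(a), compositional_complexity(b))
  expect_false(isTRUE(all.equal(configurational_complexity(a),
                                configurational_complexity(b))))
  # a single repeated shape has zero configurational complexity
  expect_equal(configurational_complexity(grid_item(matrix(4L, 3, 3), "assembly")), 0)
  # brute-force recomputation of the full pipeline on one fixture
  m <- matrix(c(1L, 5L, 9L, 14L), 2, 2)
  item <- grid_item(m, "assembly")
  f <- oracle_cooccurrence(m, c("0", "45", "90", "135"))
  W <- shape_pair_weights()
  p <- f / sum(f)
  nz <- p > 0
  expect_equal(configurational_complexity(item),
               -sum(W[nz] * p[nz] * log2(p[nz])))
})

test_that("play complexity gates the compositional term through the sigmoid", {
  params <- complexity_params()
  # identical triangles: large C_compos but C_config = 0, so C_play stays small
  tri <- grid_item(matrix(9L, 2, 2), "assembly")
  bd <- play_complexity(tri, params)
  expect_equal(bd$c_config, 0)
  expect_gt(bd$c_compos, 18)
  expect_equal(bd$c_play, bd$k * bd$c_compos)
  expect_lt(bd$c_play, 3)
  # sigmoid midpoint: k(beta) = 0.5
  expect_equal(cubecat:::sigmoid_k(params$sigmoid_beta, params), 0.5)
  # breakdown composes exactly
  g <- grid_item(matrix(c(1L, 8L, 2L, 7L), 2, 2), "assembly")
  bd <- play_complexity(g, params)
  expect_equal(bd$c_play, bd$k * bd$c_compos + bd$c_config)
  # monotone in C_config at fixed C_compos
  ids <- c(3L, 3L, 3L, 6L, 6L, 6L, 9L, 9L, 9L)
  a <- play_complexity(grid_item(matrix(ids, 3, 3), "assembly"))
  b <- play_complexity(grid_item(matrix(ids[c(1, 4, 7, 2, 5, 8, 3, 6, 9)], 3, 3),
                                 "assembly"))
  expect_equal(a$c_compos, b$c_compos)
  expect_lt(a$c_config, b$c_config)
  expect_lt(a$c_play, b$c_play)
  # determinism: identical input, bit-identical output
  expect_identical(play_complexity(g), play_complexity(g))
})

test_that("shape-matching uses configurational complexity alone, over 3 matrices", {
  base <- grid_item(matrix(c(3L, 6L, 6L, 3L), 2, 2), "shape_matching")
  it <- shape_matching_item(base, c(0, 0))
  bd <- play_complexity(it)
  expect_equal(bd$c_play, bd$c_config)
  manual <- weighted_entropy(build_cooccurrence(base, "0")) +
    weighted_entropy(build_cooccurrence(base, "90")) +
    weighted_entropy(build_cooccurrence(base, c("45", "135")))
  expect_equal(bd$c_play, manual)
})

test_that("sequence complexity uses circulant 0-degree pairs along the sequence", {
  s <- sequence_item(c(1L, 5L, 9L, 13L))
  manual <- weighted_entropy(
    build_cooccurrence(matrix(s$shapes, 1), "0", circulant = TRUE))
  expect_equal(play_complexity(s)$c_config, manual)
  # single-shape sequence has no pairs
  expect_equal(play_complexity(sequence_item(3L))$c_config, 0)
})
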