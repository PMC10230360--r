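test_that("fixed scoring reproduces the printed point tables", {
  o <- function(...) outcome(...)
  # Assembly 2x2: 3 points within 15 s, 2 points within 30 s
  expect_equal(score_fixed(o("assembly", TRUE, 10, item_dims = c(2, 2))), 3L)
  expect_equal(score_fixed(o("assembly", TRUE, 20, item_dims = c(2, 2))), 2L)
  expect_equal(score_fixed(o("assembly", TRUE, 31, item_dims = c(2, 2))), 0L)
  # Assembly 3x3: 4 / 3 / 2 points within 30 / 40 / 60 s
  expect_equal(score_fixed(o("assembly", TRUE, 25, item_dims = c(3, 3))), 4L)
  expect_equal(score_fixed(o("assembly", TRUE, 35, item_dims = c(3, 3))), 3L)
  expect_equal(score_fixed(o("assembly", TRUE, 50, item_dims = c(3, 3))), 2L)
  expect_equal(score_fixed(o("assembly", TRUE, 61, item_dims = c(3, 3))), 0L)
  # untimed games: 2 points per correct answer, regardless of time
  for (g in c("shape_matching", "sequence_memory", "spatial_memory")) {
    expect_equal(score_fixed(o(g, TRUE, 500)), 2L)
    expect_equal(score_fixed(o(g, FALSE, 1)), 0L)
  }
  # Path-Tracking: shortest 4/2/1 within 20/40/80 s; non-shortest 2/1 within 20/40 s
  expect_equal(score_fixed(o("path_tracking", TRUE, 15, took_shortest = TRUE)), 4L)
  expect_equal(score_fixed(o("path_tracking", TRUE, 30, took_shortest = TRUE)), 2L)
  expect_equal(score_fixed(o("path_tracking", TRUE, 70, took_shortest = TRUE)), 1L)
  expect_equal(score_fixed(o("path_tracking", TRUE, 15, took_shortest = FALSE)), 2L)
  expect_equal(score_fixed(o("path_tracking", TRUE, 30, took_shortest = FALSE)), 1L)
  expect_equal(score_fixed(o("path_tracking", TRUE, 50, took_shortest = FALSE)), 0L)
  # Maze: shortest 4/2/1 within 10/20/40 s; non-shortest 2/1 within 10/20 s
  expect_equal(score_fixed(o("maze", TRUE, 8, took_shortest = TRUE)), 4L)
  expect_equal(score_fixed(o("maze", TRUE, 15, took_shortest = TRUE)), 2L)
  expect_equal(score_fixed(o("maze", TRUE, 30, took_shortest = TRUE)), 1L)
  expect_equal(score_fixed(o("maze", TRUE, 15, took_shortest = FALSE)), 1L)
  expect_equal(score_fixed(o("maze", TRUE, 45, took_shortest = TRUE)), 0L)
  # incorrect always scores 0
  expect_equal(score_fixed(o("maze", FALSE, 5, took_shortest = TRUE)), 0L)
})

test_that("time-band boundaries are inclusive on the left band", {
  o <- function(t, dims = c(2, 2)) outcome("assembly", TRUE, t, item_dims = dims)
  # 'within 15 seconds' includes exactly 15; 'between 15 and 30' includes 30
  expect_equal(score_fixed(o(0)), 3L)
  expect_equal(score_fixed(o(15)), 3L)
  expect_equal(score_fixed(o(15 + 1e-9)), 2L)
  expect_equal(score_fixed(o(30)), 2L)
  expect_equal(score_fixed(o(30 + 1e-9)), 0L)
  # exhaustive sweep over every printed boundary in every table
  bands <- list(
    list(g = "assembly", dims = c(2, 2), short = NULL, cuts = c(15, 30), pts = c(3, 2)),
    list(g = "assembly", dims = c(3, 3), short = NULL, cuts = c(30, 40, 60), pts = c(4, 3, 2)),
    list(g = "path_tracking", dims = NULL, short = TRUE, cuts = c(20, 40, 80), pts = c(4, 2, 1)),
    list(g = "path_tracking", dims = NULL, short = FALSE, cuts = c(20, 40), pts = c(2, 1)),
    list(g = "maze", dims = NULL, short = TRUE, cuts = c(10, 20, 40), pts = c(4, 2, 1)),
    list(g = "maze", dims = NULL, short = FALSE, cuts = c(10, 20), pts = c(2, 1))
  )
  for (b in bands) {
    for (i in seq_along(b$cuts)) {
      at <- outcome(b$g, TRUE, b$cuts[i], item_dims = b$dims, took_shortest = b$short)
      above <- outcome(b$g, TRUE, b$cuts[i] + 0.001, item_dims = b$dims,
                       took_shortest = b$short)
      expect_equal(score_fixed(at), as.integer(b$pts[i]),
                   label = sprintf("%s at %g s", b$g, b$cuts[i]))
      expected_above <- if (i < length(b$cuts)) as.integer(b$pts[i + 1]) else 0L
      expect_equal(score_fixed(above), expected_above,
                   label = sprintf("%s just above %g s", b$g, b$cuts[i]))
    }
  }
})

test_that("adaptive scoring applies the repeat and post-revert deductions", {
  o22 <- outcome("assembly", TRUE, 10, item_dims = c(2, 2))
  # repeated at the same complexity: one point less than fixed
  expect_equal(score_adaptive(o22, list(repeated_same_complexity = TRUE)), 2L)
  # correct after two misses: exactly one point
  expect_equal(score_adaptive(o22, list(after_two_misses = TRUE)), 1L)
  # no context flags: the fixed score
  expect_equal(score_adaptive(o22), 3L)
  # incorrect scores zero in any context
  miss <- outcome("assembly", FALSE, 10, item_dims = c(2, 2))
  expect_equal(score_adaptive(miss, list(repeated_same_complexity = TRUE)), 0L)
  # deduction floors at zero and never exceeds the fixed score
  slow <- outcome("assembly", TRUE, 100, item_dims = c(2, 2))
  expect_equal(score_adaptive(slow, list(repeated_same_complexity = TRUE)), 0L)
  expect_lte(score_adaptive(slow, list(after_two_misses = TRUE)),
             score_fixed(slow))
  # mutually exclusive flags
  expect_error(
    score_adaptive(o22, list(repeated_same_complexity = TRUE,
                             after_two_misses = TRUE)),
    "mutually exclusive"
  )
})

test_that("scores are nonincreasing in completion time", {
  for (g in c("path_tracking", "maze")) {
    times <- seq(0, 100, 2.5)
    sc <- vapply(times, function(t) {
      score_fixed(outcome(g, TRUE, t, took_shortest = TRUE))
    }, integer(1))
    expect_true(all(diff(sc) <= 0))
  }
  sc <- vapply(seq(0, 70, 1), function(t) {
    score_fixed(outcome("assembly", TRUE, t, item_dims = c(3, 3)))
  }, integer(1))
  expect_true(all(diff(sc) <= 0))
})
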