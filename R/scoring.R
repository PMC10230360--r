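#' Response outcome for scoring
#'
#' @param game Game name.
#' @param correct Logical correctness.
#' @param completion_time Seconds, >= 0.
#' @param item_dims `(rows, cols)` for Assembly items (band selection depends
#'   on item size); ignored elsewhere.
#' @param took_shortest For Path-Tracking/Maze: whether the traced path was
#'   the shortest one.
#' @return An object of class `outcome`.
#' @export
outcome <- function(game, correct, completion_time, item_dims = NULL,
                    took_shortest = NULL) {
  game <- match.arg(game, cubecat_games)
  stopifnot(is.logical(correct), length(correct) == 1L,
            is.numeric(completion_time), completion_time >= 0)
  if (game == "assembly" && is.null(item_dims)) {
    stop("Assembly outcomes need `item_dims`", call. = FALSE)
  }
  if (game %in% c("path_tracking", "maze") && is.null(took_shortest)) {
    stop(game, " outcomes need `took_shortest`", call. = FALSE)
  }
  structure(list(game = game, correct = correct,
                 completion_time = completion_time,
                 item_dims = item_dims, took_shortest = took_shortest),
            class = "outcome")
}

#' Scoring tables
#'
#' The point tables of the fixed-version games, overridable for
#' standardisation experiments. Time bands are half-open on the left:
#' "within 15 seconds" means `[0, 15]` and "between 15 and 30" means
#' `(15, 30]`; anything not matching a band scores 0.
#'
#' @return A nested list: per game, either `points_correct` (untimed games)
#'   or band definitions (`cuts` = upper time limits, `points` = award per
#'   band, last implicit band scoring 0).
#' @export
scoring_tables <- function() {
  list(
    assembly = list(
      "2" = list(cuts = c(15, 30), points = c(3L, 2L)),
      "3" = list(cuts = c(30, 40, 60), points = c(4L, 3L, 2L))
    ),
    shape_matching = list(points_correct = 2L),
    sequence_memory = list(points_correct = 2L),
    spatial_memory = list(points_correct = 2L),
    path_tracking = list(
      shortest = list(cuts = c(20, 40, 80), points = c(4L, 2L, 1L)),
      not_shortest = list(cuts = c(20, 40), points = c(2L, 1L))
    ),
    maze = list(
      shortest = list(cuts = c(10, 20, 40), points = c(4L, 2L, 1L)),
      not_shortest = list(cuts = c(10, 20), points = c(2L, 1L))
    )
  )
}

# award for a completion time under a band table; bands are (lo, hi]
band_points <- function(time, band) {
  i <- findInterval(time, band$cuts, left.open = TRUE)
  if (i >= length(band$points) + 1L) 0L else c(band$points, 0L)[i + 1L]
}

#' Fixed-version score of an outcome
#'
#' Assembly awards depend on item size and time (2x2: 3/2 points within 15 s
#' / within 30 s; 3x3: 4/3/2 points within 30/40/60 s). Shape-Matching,
#' Sequence-Memory and Spatial-Memory are untimed: 2 points for a correct
#' answer. Path-Tracking and Maze depend on time and on whether the traced
#' path was the shortest. Anything else scores 0.
#'
#' @param x An [outcome()].
#' @param tables Scoring tables (default [scoring_tables()]).
#' @return Integer points >= 0.
#' @export
#' @examples
#' score_fixed(outcome("assembly", TRUE, 10, item_dims = c(2, 2)))
score_fixed <- function(x, tables = scoring_tables()) {
  stopifnot(inherits(x, "outcome"))
  tab <- tables[[x$game]]
  if (is.null(tab)) stop("no scoring table for game ", x$game, call. = FALSE)
  if (!x$correct) return(0L)
  if (!is.null(tab$points_correct)) return(tab$points_correct)
  if (x$game == "assembly") {
    band <- tab[[as.character(x$item_dims[1])]]
    if (is.null(band)) stop("no Assembly band for ", x$item_dims[1], "x",
                            x$item_dims[2], " items", call. = FALSE)
    return(band_points(x$completion_time, band))
  }
  band <- if (isTRUE(x$took_shortest)) tab$shortest else tab$not_shortest
  band_points(x$completion_time, band)
}

#' Adaptive-version score of an outcome
#'
#' Two deductions modify the fixed score: a correct answer on an item
#' regenerated at the same complexity as a previously missed one earns 1
#' point less than the fixed award (floored at 0); a correct answer on the
#' easier item generated after two consecutive misses earns exactly 1 point.
#' Incorrect answers score 0 in every context.
#'
#' @param x An [outcome()].
#' @param context A list with mutually exclusive logical flags
#'   `repeated_same_complexity` and `after_two_misses`.
#' @param tables Scoring tables (default [scoring_tables()]).
#' @return Integer points >= 0, never exceeding the fixed score.
#' @export
score_adaptive <- function(x, context = list(repeated_same_complexity = FALSE,
                                             after_two_misses = FALSE),
                           tables = scoring_tables()) {
  rep_same <- isTRUE(context$repeated_same_complexity)
  after2 <- isTRUE(context$after_two_misses)
  if (rep_same && after2) {
    stop("context flags repeated_same_complexity and after_two_misses are ",
         "mutually exclusive", call. = FALSE)
  }
  if (!x$correct) return(0L)
  base <- score_fixed(x, tables)
  if (after2) return(min(1L, base))
  if (rep_same) return(max(base - 1L, 0L))
  base
}
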