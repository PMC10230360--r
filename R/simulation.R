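#' Simulated examinee model
#'
#' A stand-in for a human player, calibrated so that accuracy decreases and
#' completion time increases with play complexity. Correctness is logistic in
#' the gap between item complexity and ability,
#' `P(correct) = 1 / (1 + exp(slope * (C_play - ability)))`, and completion
#' time is linear in complexity with truncated-normal noise,
#' `time = max(0, base_time + time_slope * C_play + N(0, time_noise_sd))`.
#'
#' @param ability Ability on the play-complexity scale: the complexity at
#'   which the examinee answers correctly half the time.
#' @param slope Discrimination > 0 (default 1 per complexity unit).
#' @param base_time Seconds at zero complexity (default 5).
#' @param time_slope Seconds per complexity unit (default 2).
#' @param time_noise_sd Response-time noise SD in seconds (default 1).
#' @return An object of class `player_model`.
#' @export
player_model <- function(ability, slope = 1, base_time = 5, time_slope = 2,
                         time_noise_sd = 1) {
  stopifnot(slope > 0, base_time >= 0, time_slope >= 0, time_noise_sd >= 0)
  structure(list(ability = ability, slope = slope, base_time = base_time,
                 time_slope = time_slope, time_noise_sd = time_noise_sd),
            class = "player_model")
}

#' Simulate one response
#'
#' @param player A [player_model()].
#' @param breakdown A `complexity_breakdown` (or a bare `C_play` value).
#' @return `list(correct = logical, time = seconds)`.
#' @export
respond <- function(player, breakdown) {
  stopifnot(inherits(player, "player_model"))
  cp <- if (is.numeric(breakdown)) breakdown else breakdown$c_play
  p <- 1 / (1 + exp(player$slope * (cp - player$ability)))
  correct <- stats::runif(1) < p
  time <- max(0, player$base_time + player$time_slope * cp +
                stats::rnorm(1, 0, player$time_noise_sd))
  list(correct = correct, time = time)
}

#' Responder closure over a player model
#'
#' Adapts a [player_model()] to the `function(item, breakdown)` contract of
#' [run_session()] and [run_cohort()].
#'
#' @param player A [player_model()].
#' @return A responder function.
#' @export
sim_responder <- function(player) {
  force(player)
  function(item, breakdown) respond(player, breakdown)
}

#' Spearman rank correlation with p value and Fisher-transform CI
#'
#' Rank correlation (average ranks for ties), two-sided p value from the
#' t approximation, and a confidence interval from the Fisher z transform
#' with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y Numeric vectors of equal length >= 3; either with zero rank
#'   variance is an error.
#' @param level Confidence level (default 0.95).
#' @return `list(r, p, lo, hi, n)`.
#' @export
spearman_ci <- function(x, y, level = 0.95) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("zero rank variance; Spearman correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  )
  if (abs(r) >= 1 - 1e-15) {
    lo <- hi <- r  # degenerate: Fisher z diverges at |r| = 1
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    lo <- tanh(z - q * se)
    hi <- tanh(z + q * se)
  }
  list(r = r, p = p, lo = lo, hi = hi, n = n)
}

#' Simulate a cohort and correlate complexity with performance
#'
#' Re-enacts the complexity-validation design in silico: a cohort of
#' simulated examinees plays a game, and per-item mean correctness and mean
#' completion time are correlated (Spearman) with the items' `C_play`
#' values. A valid complexity measure shows a positive time correlation and
#' — where correctness varies — a negative correctness correlation. In fixed
#' mode every player answers the same item schedule; in adaptive mode each
#' player runs the dynamic-difficulty engine and per-player final
#' complexities are reported instead of per-item aggregates.
#'
#' @param game Game name.
#' @param mode `"fixed"` or `"adaptive"`.
#' @param n_players Cohort size, >= 3 (defaults: 38 fixed, 42 adaptive,
#'   mirroring typical group sizes for such evaluations).
#' @param item_schedule Fixed mode: a list of `generate_item()` results (or
#'   any list with `item` + `breakdown` fields).
#' @param players Optional list of [player_model()]s; by default abilities
#'   are drawn uniformly over the middle 80% of the schedule's complexity
#'   range.
#' @param gen_config,adapt_config Adaptive mode: passed to [run_session()].
#' @param seed Optional seed.
#' @param params [complexity_params()].
#' @return A `cohort_result`: for fixed mode, `per_item` (data frame with
#'   `c_play`, `mean_correct`, `mean_time`) and `correlations` (list with
#'   `time` and `correctness` [spearman_ci()] results; a correlation that is
#'   undefined because the aggregate has zero rank variance is returned as
#'   `NULL` with a flag in `flags`). For adaptive mode, `sessions` and
#'   `final_c` per player.
#' @export
run_cohort <- function(game, mode = c("fixed", "adaptive"),
                       n_players = NULL, item_schedule = NULL, players = NULL,
                       gen_config = NULL, adapt_config = NULL, seed = NULL,
                       params = complexity_params()) {
  mode <- match.arg(mode)
  game <- match.arg(game, cubecat_games)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_players)) n_players <- if (mode == "fixed") 38L else 42L
  if (n_players < 3L) stop("need at least 3 players for correlation", call. = FALSE)

  if (mode == "fixed") {
    if (is.null(item_schedule)) stop("fixed mode needs an `item_schedule`", call. = FALSE)
    cp <- vapply(item_schedule, function(it) it$breakdown$c_play, numeric(1))
    if (is.null(players)) {
      span <- range(cp)
      lo <- span[1] + 0.1 * diff(span); hi <- span[2] - 0.1 * diff(span)
      players <- lapply(stats::runif(n_players, lo, hi), player_model)
    }
    n_items <- length(item_schedule)
    correct <- matrix(NA, n_players, n_items)
    times <- matrix(NA_real_, n_players, n_items)
    for (pl in seq_len(n_players)) {
      for (it in seq_len(n_items)) {
        resp <- respond(players[[pl]], item_schedule[[it]]$breakdown)
        correct[pl, it] <- resp$correct
        times[pl, it] <- resp$time
      }
    }
    per_item <- data.frame(
      item = seq_len(n_items), c_play = cp,
      mean_correct = colMeans(correct), mean_time = colMeans(times)
    )
    corr <- list(time = NULL, correctness = NULL)
    flags <- character()
    corr$time <- tryCatch(spearman_ci(per_item$c_play, per_item$mean_time),
                          error = function(e) { flags <<- c(flags, "time_undefined"); NULL })
    corr$correctness <- tryCatch(spearman_ci(per_item$c_play, per_item$mean_correct),
                                 error = function(e) { flags <<- c(flags, "correctness_undefined"); NULL })
    return(structure(list(game = game, mode = mode, n_players = n_players,
                          per_item = per_item, correlations = corr,
                          flags = flags),
                     class = "cohort_result"))
  }

  # adaptive mode
  if (is.null(gen_config) || is.null(adapt_config)) {
    stop("adaptive mode needs `gen_config` and `adapt_config`", call. = FALSE)
  }
  if (is.null(players)) {
    lo <- adapt_config$start_c + 0.1 * (adapt_config$ceiling_c - adapt_config$start_c)
    hi <- adapt_config$ceiling_c - 0.1 * (adapt_config$ceiling_c - adapt_config$start_c)
    players <- lapply(stats::runif(n_players, lo, hi), player_model)
  }
  sessions <- lapply(players, function(pl) {
    run_session(game, sim_responder(pl), gen_config, adapt_config, params = params)
  })
  structure(list(
    game = game, mode = mode, n_players = n_players,
    sessions = sessions,
    ability = vapply(players, `[[`, numeric(1), "ability"),
    final_c = vapply(sessions, `[[`, numeric(1), "final_c"),
    total_score = vapply(sessions, `[[`, numeric(1), "total_score")
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result: %s (%s), n = %d>\n", x$game, x$mode, x$n_players))
  if (!is.null(x$correlations)) {
    for (nm in names(x$correlations)) {
      s <- x$correlations[[nm]]
      if (is.null(s)) cat(sprintf("  %s: undefined\n", nm))
      else cat(sprintf("  %-12s r = %+.3f  p = %.4g  95%% CI [%.3f, %.3f]\n",
                       nm, s$r, s$p, s$lo, s$hi))
    }
  }
  invisible(x)
}
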