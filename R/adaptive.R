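#' Adaptive engine configuration
#'
#' Parameters of the rule-based dynamic-difficulty engine: play starts at a
#' predefined low complexity `start_c` and climbs by `up_step` after each
#' correct answer up to the ceiling `ceiling_c`; a session ends when a
#' correct answer is given at the ceiling, when the magnitude of a
#' complexity step falls below `min_step`, or after `max_items` items.
#'
#' @param start_c Starting (low) complexity.
#' @param ceiling_c Highest complexity; must exceed `start_c`.
#' @param up_step Complexity increment after a correct answer (default 0.5).
#' @param min_step Termination threshold on the step magnitude (default 0.05);
#'   must satisfy `up_step > min_step > 0`.
#' @param max_items Safety cap on items per session (default 25).
#' @return An object of class `adaptive_config`.
#' @export
adaptive_config <- function(start_c, ceiling_c, up_step = 0.5,
                            min_step = 0.05, max_items = 25L) {
  stopifnot(start_c < ceiling_c, up_step > min_step, min_step > 0,
            max_items >= 1L)
  structure(list(start_c = start_c, ceiling_c = ceiling_c, up_step = up_step,
                 min_step = min_step, max_items = as.integer(max_items)),
            class = "adaptive_config")
}

#' Fresh adaptive state
#'
#' @param config An [adaptive_config()].
#' @return An object of class `adaptive_state` holding the current target
#'   complexity, the latest correctly-answered complexity (anchored at
#'   `start_c` before any correct answer), the last step and its kind
#'   (`"init"`, `"advance"`, `"same"`, `"revert"`), the consecutive-incorrect
#'   counter, the item count and the termination flag.
#' @export
new_adaptive_state <- function(config) {
  stopifnot(inherits(config, "adaptive_config"))
  structure(list(
    current_c = config$start_c, last_correct_c = NULL,
    step = NA_real_, step_type = "init",
    consecutive_incorrect = 0L, n_items = 0L,
    last_correct = NA, correct_at_ceiling = FALSE,
    terminated = FALSE
  ), class = "adaptive_state")
}

#' @export
print.adaptive_state <- function(x, ...) {
  cat(sprintf("<adaptive_state: target %.3f, %d items, %s>\n",
              x$current_c, x$n_items,
              if (x$terminated) "terminated" else "active"))
  invisible(x)
}

#' Advance the adaptive state with one response
#'
#' Applies the dynamic-difficulty rule: a correct answer moves the target up
#' by `up_step` (capped at the ceiling, which is absorbing); a first
#' incorrect answer regenerates an item at the same complexity; a second
#' consecutive incorrect answer reverts the target to the midpoint between
#' the latest correctly-answered complexity (the start complexity if none
#' yet) and the current one. The signed step (next minus current target) and
#' its kind are recorded.
#'
#' @param state An [new_adaptive_state()] result (not terminated).
#' @param correct Logical response to the item just administered at
#'   `state$current_c`.
#' @param config The [adaptive_config()].
#' @return The updated `adaptive_state`.
#' @export
update_adaptive <- function(state, correct, config) {
  stopifnot(inherits(state, "adaptive_state"), inherits(config, "adaptive_config"),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  if (state$terminated) {
    stop("adaptive state is terminated; no further updates accepted", call. = FALSE)
  }
  cur <- state$current_c
  state$n_items <- state$n_items + 1L
  state$last_correct <- correct
  state$correct_at_ceiling <- correct && cur >= config$ceiling_c - 1e-12
  if (correct) {
    state$last_correct_c <- cur
    nxt <- min(cur + config$up_step, config$ceiling_c)
    state$consecutive_incorrect <- 0L
    state$step_type <- "advance"
  } else if (state$consecutive_incorrect == 0L) {
    nxt <- cur
    state$consecutive_incorrect <- 1L
    state$step_type <- "same"
  } else {
    anchor <- if (is.null(state$last_correct_c)) config$start_c else state$last_correct_c
    nxt <- (anchor + cur) / 2
    state$consecutive_incorrect <- 0L
    state$step_type <- "revert"
  }
  state$step <- nxt - cur
  state$current_c <- nxt
  state
}

#' Should the adaptive session end?
#'
#' True when a correct answer was given at the ceiling complexity, when the
#' last advance or revert step was smaller in magnitude than `min_step`, or
#' when `max_items` items have been administered. The zero step of a
#' same-complexity regeneration (a single miss) never triggers termination —
#' play continues with a new item at the same complexity.
#'
#' @param state An `adaptive_state`.
#' @param config The [adaptive_config()].
#' @return Logical.
#' @export
should_terminate <- function(state, config) {
  stopifnot(inherits(state, "adaptive_state"), inherits(config, "adaptive_config"))
  if (isTRUE(state$correct_at_ceiling)) return(TRUE)
  if (state$step_type %in% c("advance", "revert") &&
      !is.na(state$step) && abs(state$step) < config$min_step) return(TRUE)
  state$n_items >= config$max_items
}

#' Responder that answers correctly below a threshold complexity
#'
#' A deterministic examinee model: correct iff the item's `C_play` is below
#' `theta`; completion time is a fixed constant. Useful for engine
#' diagnostics and ability-recovery checks.
#'
#' @param theta Threshold on `C_play`.
#' @param time Constant completion time in seconds (default 5).
#' @return A responder `function(item, breakdown)` returning
#'   `list(correct, time)`.
#' @export
threshold_responder <- function(theta, time = 5) {
  force(theta); force(time)
  function(item, breakdown) list(correct = breakdown$c_play < theta, time = time)
}

#' Run a full adaptive session
#'
#' Orchestrates the loop: generate an item at the current target complexity,
#' obtain a response from the responder, score it with the adaptive scoring
#' rules, update the dynamic-difficulty state, and stop when
#' [should_terminate()] fires. Termination is guaranteed: midpoint reverts
#' contract the step magnitude and `max_items` bounds the rest.
#'
#' @param game Game name.
#' @param responder A `function(item, breakdown)` returning
#'   `list(correct = logical, time = numeric)`; see [threshold_responder()]
#'   and [sim_responder()].
#' @param gen_config A [generator_config()]; its `c_d` field is overridden by
#'   the engine's moving target.
#' @param adapt_config An [adaptive_config()].
#' @param seed Optional integer seed set before the first item.
#' @param params [complexity_params()].
#' @return A `session_log`: `meta` (game, mode, seed, config snapshots) and
#'   `records`, one per item, each holding the item, its complexity
#'   breakdown, the target complexity, the response, the score and the
#'   adaptive step taken; plus `total_score` and `final_c` (last target
#'   complexity administered).
#' @export
run_session <- function(game, responder, gen_config, adapt_config, seed = NULL,
                        params = complexity_params()) {
  stopifnot(is.function(responder))
  if (!is.null(seed)) set.seed(seed)
  state <- new_adaptive_state(adapt_config)
  records <- list()
  repeat {
    target <- state$current_c
    gcfg <- gen_config
    gcfg$c_d <- target
    gcfg$seed <- NULL  # one RNG stream for the whole session
    gen <- tryCatch(generate_item(game, gcfg, params), cubecat_infeasible = function(e) {
      stop("item generation infeasible at target ", signif(target, 4),
           " during ", game, " session: ", conditionMessage(e), call. = FALSE)
    })
    resp <- responder(gen$item, gen$breakdown)
    context <- list(
      repeated_same_complexity = identical(state$step_type, "same"),
      after_two_misses = identical(state$step_type, "revert")
    )
    outc <- outcome(
      game = game, correct = isTRUE(resp$correct),
      completion_time = resp$time,
      item_dims = if (inherits(gen$item, "grid_item")) dim(gen$item$cells),
      took_shortest = if (game %in% c("path_tracking", "maze")) isTRUE(resp$correct)
    )
    sc <- score_adaptive(outc, context)
    state <- update_adaptive(state, isTRUE(resp$correct), adapt_config)
    records[[length(records) + 1L]] <- list(
      index = length(records) + 1L, target_c = target,
      item = gen$item, c_play = gen$breakdown$c_play,
      correct = isTRUE(resp$correct), time = resp$time, score = sc,
      step = state$step, step_type = state$step_type
    )
    if (should_terminate(state, adapt_config)) break
  }
  state$terminated <- TRUE
  structure(list(
    meta = list(game = game, mode = "adaptive", seed = seed,
                gen_config = unclass(gen_config),
                adapt_config = unclass(adapt_config),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    records = records,
    total_score = sum(vapply(records, `[[`, numeric(1), "score")),
    final_c = records[[length(records)]]$target_c,
    n_items = length(records)
  ), class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log: %s (%s), %d items, total score %g>\n",
              x$meta$game, x$meta$mode, x$n_items, x$total_score))
  invisible(x)
}
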