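validation_error <- function(msg) {
  stop(structure(class = c("cubecat_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Write a session log to JSON
#'
#' Serialises a [run_session()] log — metadata, per-item records with inline
#' items in the interchange schema, scores and adaptive steps — so that
#' `read_session(write_session(x)) == x`.
#'
#' @param log A `session_log`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  recs <- lapply(log$records, function(r) {
    r$item <- item_to_list(r$item)
    r
  })
  jsonlite::write_json(
    list(meta = log$meta, records = recs, total_score = log$total_score,
         final_c = log$final_c, n_items = log$n_items),
    path, auto_unbox = TRUE, digits = 17, null = "null"  # 17: exact doubles
  )
  invisible(path)
}

#' Read a session log from JSON
#'
#' Validates the schema (missing or malformed fields raise a
#' `cubecat_validation_error` naming the field; a truncated or unparsable
#' file raises the same, never a crash) and reconstructs the items.
#'
#' @param path File path written by [write_session()].
#' @return A `session_log`.
#' @export
read_session <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) validation_error(
                  paste0("cannot parse session file: ", conditionMessage(e))))
  for (field in c("meta", "records", "total_score", "n_items")) {
    if (is.null(x[[field]])) validation_error(paste0("missing field: ", field))
  }
  if (is.null(x$meta$game)) validation_error("missing field: meta.game")
  records <- lapply(x$records, function(r) {
    for (field in c("index", "target_c", "item", "correct", "time", "score")) {
      if (is.null(r[[field]])) {
        validation_error(paste0("record ", r$index %||% "?",
                                ": missing field: ", field))
      }
    }
    r$item <- item_from_list(r$item)
    # the interchange schema stores mazes unsolved; restore the solver state
    if (inherits(r$item, "maze_item")) r$item <- astar_shortest(r$item)
    r$index <- as.integer(r$index)
    r$score <- as.integer(r$score)
    r$correct <- as.logical(r$correct)
    if (!is.null(r$step)) r$step <- as.numeric(r$step)
    r
  })
  if (length(records)) {
    total <- sum(vapply(records, `[[`, numeric(1), "score"))
    if (abs(total - x$total_score) > 1e-9) {
      validation_error("total_score does not equal the sum of record scores")
    }
  }
  structure(list(
    meta = x$meta, records = records,
    total_score = as.numeric(x$total_score),
    final_c = if (!is.null(x$final_c)) as.numeric(x$final_c),
    n_items = as.integer(x$n_items)
  ), class = "session_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default configuration
#'
#' The package defaults for the generator, the adaptive engine and the
#' complexity parameters, as one nested list matching the YAML configuration
#' schema of [load_config()].
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    generator = list(tol = 0.25, max_iterations = 5000L),
    adaptive = list(up_step = 0.5, min_step = 0.05, max_items = 25L),
    complexity = list(sigmoid_alpha = 1, sigmoid_beta = 2,
                      maze_scale = 0.4, maze_inner_scale = 10,
                      faces_per_cube = 6)
  )
}

merge_config <- function(defaults, overrides, prefix = "") {
  for (key in names(overrides)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults)) {
      validation_error(paste0("unknown configuration key: ", full))
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(overrides[[key]])) {
        validation_error(paste0("configuration key ", full, " must be a section"))
      }
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      paste0(full, "."))
    } else {
      if (!is.numeric(overrides[[key]]) || length(overrides[[key]]) != 1L) {
        validation_error(paste0("configuration key ", full,
                                " must be a single number"))
      }
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Load a YAML configuration over the defaults
#'
#' Reads a YAML file and overlays it on [default_config()]. Unknown keys are
#' rejected (with the offending key named) rather than silently ignored, and
#' every value must be a single number. An empty file yields the defaults.
#'
#' @param path YAML file path.
#' @return The merged nested configuration list.
#' @export
load_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) return(default_config())
  if (!is.list(overrides)) validation_error("configuration must be a mapping")
  merge_config(default_config(), overrides)
}

#' Build parameter objects from a merged configuration
#'
#' @param config A merged configuration list (see [load_config()]).
#' @return A list with a `complexity_params` object plus the generator and
#'   adaptive sections.
#' @export
config_params <- function(config = default_config()) {
  list(
    params = complexity_params(
      sigmoid_alpha = config$complexity$sigmoid_alpha,
      sigmoid_beta = config$complexity$sigmoid_beta,
      maze_scale = config$complexity$maze_scale,
      maze_inner_scale = config$complexity$maze_inner_scale,
      faces_per_cube = config$complexity$faces_per_cube
    ),
    generator = config$generator,
    adaptive = config$adaptive
  )
}
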