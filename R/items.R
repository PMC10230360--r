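#' Grid item (Assembly, Spatial-Memory, Shape-Matching base)
#'
#' A square arrangement of cube-face shapes; 2x2 items use 4 cubes and 3x3
#' items use 9 cubes. Cells are surface-shape ids (see [surface_shapes()]).
#' Grid coordinates are 0-based `(row, col)`, row-major.
#'
#' @param cells Integer matrix (2x2 or 3x3) of surface-shape ids.
#' @param game One of `"assembly"`, `"spatial_memory"`, `"shape_matching"`.
#' @return An object of class `grid_item`.
#' @export
#' @examples
#' grid_item(matrix(c(1, 2, 3, 4), 2, 2), "assembly")
grid_item <- function(cells, game = c("assembly", "spatial_memory", "shape_matching")) {
  game <- match.arg(game)
  if (!is.matrix(cells)) stop("`cells` must be a matrix", call. = FALSE)
  if (nrow(cells) != ncol(cells) || !nrow(cells) %in% c(2L, 3L)) {
    stop("grid items are 2x2 or 3x3", call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  assert_shape_id(as.vector(cells))
  structure(list(cells = cells, game = game), class = "grid_item")
}

#' @export
print.grid_item <- function(x, ...) {
  cat(sprintf("<grid_item: %s %dx%d>\n", x$game, nrow(x$cells), ncol(x$cells)))
  print(x$cells)
  invisible(x)
}

#' Shape-Matching item
#'
#' A patterned grid with one cell hidden; the examinee supplies the missing
#' shape. The answer is, by construction, the shape at the hidden cell of the
#' underlying pattern.
#'
#' @param base A [grid_item()] with `game = "shape_matching"`.
#' @param missing_cell 0-based `(row, col)` of the hidden cell.
#' @return An object of class `shape_matching_item` with fields `base`,
#'   `missing_cell`, `answer`.
#' @export
shape_matching_item <- function(base, missing_cell) {
  stopifnot(inherits(base, "grid_item"))
  if (base$game != "shape_matching") stop("base grid must be a shape_matching grid", call. = FALSE)
  mc <- as.integer(missing_cell)
  if (length(mc) != 2L || any(mc < 0L) || any(mc >= nrow(base$cells))) {
    stop("`missing_cell` must be a 0-based (row, col) inside the grid", call. = FALSE)
  }
  structure(list(
    base = base, missing_cell = mc,
    answer = base$cells[mc[1] + 1L, mc[2] + 1L]
  ), class = "shape_matching_item")
}

#' @export
print.shape_matching_item <- function(x, ...) {
  cat(sprintf("<shape_matching_item: hidden (%d,%d), answer %d>\n",
              x$missing_cell[1], x$missing_cell[2], x$answer))
  print(x$base$cells)
  invisible(x)
}

#' Sequence-Memory item
#'
#' An ordered sequence of shapes, each displayed for one second, to be
#' reconstructed from memory with a single cube.
#'
#' @param shapes Integer vector of surface-shape ids, length >= 1.
#' @return An object of class `sequence_item`.
#' @export
sequence_item <- function(shapes) {
  shapes <- as.integer(shapes)
  if (length(shapes) < 1L) stop("a sequence item needs at least one shape", call. = FALSE)
  assert_shape_id(shapes)
  structure(list(shapes = shapes, display_seconds_per_shape = 1),
            class = "sequence_item")
}

#' @export
print.sequence_item <- function(x, ...) {
  cat("<sequence_item:", paste(x$shapes, collapse = " "), ">\n")
  invisible(x)
}

#' Path-Tracking item
#'
#' A self-avoiding connected path on a 5x5 dot grid between two endpoint
#' markers; the examinee traces it with a single cube. Vertex degrees follow
#' the path graph (endpoints 1, interior nodes 2).
#'
#' @param nodes Integer matrix, one 0-based `(row, col)` per row, consecutive
#'   rows grid-adjacent, no repeats, at least 2 nodes.
#' @param grid_dim Grid dimension (default 5).
#' @return An object of class `path_item` with fields `nodes`, `endpoints`,
#'   `degrees`, `V`, `grid_dim`.
#' @export
path_item <- function(nodes, grid_dim = 5L) {
  nodes <- matrix(as.integer(nodes), ncol = 2L)
  v <- nrow(nodes)
  if (v < 2L) stop("a path needs at least 2 nodes", call. = FALSE)
  if (any(nodes < 0L) || any(nodes >= grid_dim)) {
    stop("nodes must lie on the ", grid_dim, "x", grid_dim, " grid", call. = FALSE)
  }
  if (anyDuplicated(paste(nodes[, 1], nodes[, 2]))) {
    stop("path must be self-avoiding", call. = FALSE)
  }
  steps <- abs(diff(nodes[, 1])) + abs(diff(nodes[, 2]))
  if (any(steps != 1L)) stop("consecutive nodes must be grid-adjacent", call. = FALSE)
  degrees <- rep(2L, v)
  degrees[c(1L, v)] <- 1L
  structure(list(
    nodes = nodes, endpoints = nodes[c(1L, v), , drop = FALSE],
    degrees = degrees, V = v, grid_dim = as.integer(grid_dim)
  ), class = "path_item")
}

#' @export
print.path_item <- function(x, ...) {
  cat(sprintf("<path_item: %d nodes on %dx%d grid>\n", x$V, x$grid_dim, x$grid_dim))
  invisible(x)
}

# flood fill over open walls; returns logical reachability from start
maze_reach <- function(dim, open_right, open_down, start) {
  reach <- matrix(FALSE, dim, dim)
  queue <- matrix(start, ncol = 2L)
  reach[start[1] + 1L, start[2] + 1L] <- TRUE
  while (nrow(queue) > 0L) {
    cell <- queue[1L, ]
    queue <- queue[-1L, , drop = FALSE]
    i <- cell[1] + 1L; j <- cell[2] + 1L
    nbr <- list()
    if (j < dim && open_right[i, j]) nbr <- c(nbr, list(c(i, j + 1L)))
    if (j > 1L && open_right[i, j - 1L]) nbr <- c(nbr, list(c(i, j - 1L)))
    if (i < dim && open_down[i, j]) nbr <- c(nbr, list(c(i + 1L, j)))
    if (i > 1L && open_down[i - 1L, j]) nbr <- c(nbr, list(c(i - 1L, j)))
    for (nb in nbr) {
      if (!reach[nb[1], nb[2]]) {
        reach[nb[1], nb[2]] <- TRUE
        queue <- rbind(queue, nb - 1L)
      }
    }
  }
  reach
}

#' Maze item
#'
#' A `dim` x `dim` grid maze described by its open internal walls, with start
#' (blue) and end (red) cells. The solution slot is filled by
#' [astar_shortest()]: the minimal-length cell sequence, its length `L`
#' (number of cells, both endpoints included) and the maze-graph degree of
#' each solution cell.
#'
#' @param dim Grid dimension, >= 2.
#' @param open_right `dim x dim` logical; `[i, j]` is `TRUE` when the wall
#'   between cell `(i, j)` and `(i, j + 1)` is open (last column ignored).
#' @param open_down `dim x dim` logical; `[i, j]` is `TRUE` when the wall
#'   between `(i, j)` and `(i + 1, j)` is open (last row ignored).
#' @param start,end 0-based `(row, col)` cells; `end` must be reachable from
#'   `start`.
#' @return An object of class `maze_item`.
#' @export
maze_item <- function(dim, open_right, open_down, start, end) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L, is.matrix(open_right), is.matrix(open_down),
            all(dim(open_right) == dim), all(dim(open_down) == dim))
  start <- as.integer(start); end <- as.integer(end)
  ok_cell <- function(p) length(p) == 2L && all(p >= 0L) && all(p < dim)
  if (!ok_cell(start) || !ok_cell(end)) {
    stop("start/end must be 0-based cells inside the maze", call. = FALSE)
  }
  reach <- maze_reach(dim, open_right, open_down, start)
  if (!reach[end[1] + 1L, end[2] + 1L]) {
    stop("maze end is not reachable from start", call. = FALSE)
  }
  structure(list(
    dim = dim, open_right = open_right, open_down = open_down,
    start = start, end = end,
    solution = NULL, L = NA_integer_, solution_degrees = NULL
  ), class = "maze_item")
}

#' @export
print.maze_item <- function(x, ...) {
  cat(sprintf("<maze_item: %dx%d, start (%d,%d), end (%d,%d)%s>\n",
              x$dim, x$dim, x$start[1], x$start[2], x$end[1], x$end[2],
              if (!is.na(x$L)) sprintf(", solved L=%d", x$L) else ""))
  invisible(x)
}

#' Write or read a game item as JSON
#'
#' Items use a small JSON interchange schema keyed by `game`:
#' grids carry `rows`, `cols` and a row-major `cells` id list (plus
#' `missing_cell` for Shape-Matching); sequences carry `shapes`; paths carry
#' `nodes` and `endpoints`; mazes carry `walls` (`open_right` / `open_down`
#' row lists), `start` and `end`.
#'
#' @param item A grid/sequence/shape-matching/path/maze item.
#' @param path File path.
#' @return `write_item` returns `path` invisibly; `read_item` returns the item.
#' @export
write_item <- function(item, path) {
  jsonlite::write_json(item_to_list(item), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

item_to_list <- function(item) {
  if (inherits(item, "grid_item")) {
    list(game = item$game, rows = nrow(item$cells), cols = ncol(item$cells),
         cells = as.vector(t(item$cells)))
  } else if (inherits(item, "shape_matching_item")) {
    base <- item_to_list(item$base)
    c(base, list(missing_cell = item$missing_cell))
  } else if (inherits(item, "sequence_item")) {
    list(game = "sequence_memory", shapes = item$shapes)
  } else if (inherits(item, "path_item")) {
    list(game = "path_tracking", grid_dim = item$grid_dim,
         nodes = lapply(seq_len(item$V), function(i) item$nodes[i, ]),
         endpoints = lapply(1:2, function(i) item$endpoints[i, ]))
  } else if (inherits(item, "maze_item")) {
    list(game = "maze", dim = item$dim,
         walls = list(
           open_right = lapply(seq_len(item$dim), function(i) item$open_right[i, ]),
           open_down = lapply(seq_len(item$dim), function(i) item$open_down[i, ])
         ),
         start = item$start, end = item$end)
  } else {
    stop("not a game item", call. = FALSE)
  }
}

item_from_list <- function(x) {
  if (is.null(x$game)) stop("item JSON lacks a `game` field", call. = FALSE)
  switch(x$game,
    assembly = ,
    spatial_memory = grid_item(
      matrix(as.integer(unlist(x$cells)), x$rows, x$cols, byrow = TRUE), x$game),
    shape_matching = {
      base <- grid_item(
        matrix(as.integer(unlist(x$cells)), x$rows, x$cols, byrow = TRUE),
        "shape_matching")
      if (is.null(x$missing_cell)) base
      else shape_matching_item(base, unlist(x$missing_cell))
    },
    sequence_memory = sequence_item(unlist(x$shapes)),
    path_tracking = path_item(
      do.call(rbind, lapply(x$nodes, unlist)),
      grid_dim = if (is.null(x$grid_dim)) 5L else x$grid_dim),
    maze = maze_item(
      x$dim,
      open_right = do.call(rbind, lapply(x$walls$open_right, unlist)),
      open_down = do.call(rbind, lapply(x$walls$open_down, unlist)),
      start = unlist(x$start), end = unlist(x$end)),
    stop("unknown game in item JSON: ", x$game, call. = FALSE)
  )
}

#' @rdname write_item
#' @export
read_item <- function(path) {
  item_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
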