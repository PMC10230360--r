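#' Play-complexity parameters
#'
#' Tunable constants of the play-complexity measures. `sigmoid_alpha` and
#' `sigmoid_beta` parameterise the gate `k` that couples compositional
#' complexity into the play complexity; `maze_scale` (0.4) and
#' `maze_inner_scale` (10) are the fixed scale factors of the maze measure;
#' `faces_per_cube` is the number of distinctive faces available on each cube
#' (6 — all faces differ).
#'
#' @param sigmoid_alpha Sigmoid slope, > 0 (default 1).
#' @param sigmoid_beta Sigmoid midpoint in configurational-complexity bits
#'   (default 2).
#' @param maze_scale Outer maze scale factor (default 0.4).
#' @param maze_inner_scale Scale applied to the solution terms (default 10).
#' @param faces_per_cube Distinct faces per cube (default 6).
#' @return An object of class `complexity_params`.
#' @export
complexity_params <- function(sigmoid_alpha = 1, sigmoid_beta = 2,
                              maze_scale = 0.4, maze_inner_scale = 10,
                              faces_per_cube = 6) {
  stopifnot(sigmoid_alpha > 0, sigmoid_beta >= 0, maze_scale > 0,
            maze_inner_scale > 0, faces_per_cube >= 1)
  structure(list(
    sigmoid_alpha = sigmoid_alpha, sigmoid_beta = sigmoid_beta,
    maze_scale = maze_scale, maze_inner_scale = maze_inner_scale,
    faces_per_cube = faces_per_cube
  ), class = "complexity_params")
}

#' Shannon entropy of a probability vector (bits)
#'
#' `H = -sum(p * log2(p))` with the convention `0 * log(0) = 0`. For a
#' uniform distribution over `n` outcomes this reduces to `log2(n)`.
#'
#' @param p Nonnegative probabilities summing to 1 (tolerance 1e-8).
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2 bits
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

sigmoid_k <- function(x, params = complexity_params()) {
  1 / (1 + exp(-params$sigmoid_alpha * (x - params$sigmoid_beta)))
}

item_shape_ids <- function(item) {
  if (inherits(item, "grid_item")) as.vector(item$cells)
  else if (inherits(item, "shape_matching_item")) as.vector(item$base$cells)
  else if (inherits(item, "sequence_item")) item$shapes
  else stop("item has no shape composition", call. = FALSE)
}

#' Compositional complexity (bits)
#'
#' Information content of the shapes themselves, independent of arrangement:
#' each of the `Q` displayed shapes is one of `m` available faces shown in one
#' of its `r` distinct orientations, contributing `log2(m * r)` bits, so
#' `C_compos = sum_i log2(m_i * r_i)`. Depends only on the multiset of
#' shapes, never on their positions.
#'
#' @param item A [grid_item()], [shape_matching_item()] or [sequence_item()],
#'   or a bare vector of shape ids.
#' @param params [complexity_params()].
#' @return Compositional complexity in bits (0 for an empty item).
#' @export
compositional_complexity <- function(item, params = complexity_params()) {
  ids <- if (is.numeric(item)) as.integer(item) else item_shape_ids(item)
  if (length(ids) == 0L) return(0)
  assert_shape_id(ids)
  tax <- surface_shapes()
  folds <- tax$fold[match(ids, tax$id)]
  sum(log2(params$faces_per_cube * folds))
}

# ---- adjacent-pair extraction ------------------------------------------------

pair_directions <- c("0", "45", "90", "135")

# unit steps (row, col) per direction; 45/135 are the up-right / up-left diagonals
direction_delta <- function(direction) {
  switch(as.character(direction),
    "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(1L, 0L), "135" = c(-1L, -1L),
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

# maximal lines of 1-based row-major cell indices along a direction
grid_lines <- function(nr, nc, direction) {
  d <- direction_delta(direction)
  inb <- function(i, j) i >= 1L && i <= nr && j >= 1L && j <= nc
  lines <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    # start cells have no in-bounds predecessor
    if (inb(i - d[1], j - d[2])) next
    cells <- integer()
    ci <- i; cj <- j
    while (inb(ci, cj)) {
      cells <- c(cells, (cj - 1L) * nr + ci)  # column-major linear index
      ci <- ci + d[1]; cj <- cj + d[2]
    }
    lines[[length(lines) + 1L]] <- cells
  }
  lines
}

# memoised (from, to) index pairs for a grid shape + direction (+ circulant)
pair_indices <- function(nr, nc, direction, circulant) {
  key <- paste("pi", nr, nc, direction, circulant, sep = ".")
  if (!is.null(.cubecat[[key]])) return(.cubecat[[key]])
  from <- integer(); to <- integer()
  for (line in grid_lines(nr, nc, direction)) {
    len <- length(line)
    if (len >= 2L) {
      from <- c(from, line[-len]); to <- c(to, line[-1L])
      if (circulant) { from <- c(from, line[len]); to <- c(to, line[1L]) }
    }
  }
  .cubecat[[key]] <- cbind(from = from, to = to)
  .cubecat[[key]]
}

#' Extract ordered adjacent shape pairs along a direction
#'
#' Walks every maximal line of the grid in the given direction (0 = rightward
#' along rows, 90 = downward along columns, 45 = up-right diagonals, 135 =
#' up-left diagonals) and returns the ordered id pairs of consecutive cells.
#' With `circulant = TRUE` each line of length >= 2 is closed into a cycle by
#' the wrap-around pair from its last to its first cell; e.g. the row
#' `(3, 5, 4)` at 0 degrees yields `(3,5), (5,4), (4,3)`.
#'
#' @param grid A [grid_item()] or a plain id matrix (a sequence can be passed
#'   as a 1-row matrix).
#' @param direction One of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param circulant Include the wrap-around pair per line (default `TRUE`).
#' @return A 2-column integer matrix of ordered `(from, to)` shape ids
#'   (0 rows when the grid has no adjacent pair in that direction).
#' @export
#' @examples
#' extract_pairs(matrix(c(3, 5, 4), 1, 3), "0")
extract_pairs <- function(grid, direction, circulant = TRUE) {
  m <- if (inherits(grid, "grid_item")) grid$cells else grid
  stopifnot(is.matrix(m))
  idx <- pair_indices(nrow(m), ncol(m), direction, circulant)
  cbind(from = as.integer(m[idx[, 1]]), to = as.integer(m[idx[, 2]]))
}

#' Build the shape co-occurrence matrix
#'
#' Counts every ordered adjacent pair extracted along the requested
#' directions into a 14x14 matrix `f` indexed by shape id, the analogue of a
#' gray-level co-occurrence matrix over shape ids instead of pixel
#' intensities: `f[a, b]` is the number of extracted `(a, b)` pairs and
#' `sum(f)` the total pair count.
#'
#' @inheritParams extract_pairs
#' @param directions Character vector of directions to pool (default all four).
#' @return An integer matrix of class `cooccurrence` with attributes
#'   `directions` and `circulant`.
#' @export
build_cooccurrence <- function(grid, directions = pair_directions, circulant = TRUE) {
  n <- n_shapes()
  f <- matrix(0L, n, n)
  for (d in directions) {
    pr <- extract_pairs(grid, d, circulant)
    if (nrow(pr) > 0L) {
      cnt <- tabulate((pr[, 2] - 1L) * n + pr[, 1], nbins = n * n)
      f <- f + matrix(cnt, n, n)
    }
  }
  structure(f, class = c("cooccurrence", class(f)),
            directions = directions, circulant = circulant)
}

#' Pair weight from colour and orientation differences
#'
#' The weight of an adjacent pair is 2 when the two shapes differ in both
#' colour and orientation, and 1 otherwise.
#'
#' @param a,b Surface-shape ids (vectorised).
#' @return Integer weights in `{1, 2}`.
#' @export
pair_weight <- function(a, b) {
  assert_shape_id(c(a, b))
  tax <- surface_shapes()
  ra <- match(a, tax$id); rb <- match(b, tax$id)
  1L + as.integer(tax$color[ra] != tax$color[rb] &
                    tax$orientation[ra] != tax$orientation[rb])
}

#' Full pairwise weight matrix over the shape taxonomy
#'
#' @return A 14x14 integer matrix `W` with `W[a, b] = pair_weight(a, b)`.
#' @export
shape_pair_weights <- function() {
  if (!is.null(.cubecat$weights)) return(.cubecat$weights)
  n <- n_shapes()
  idx <- expand.grid(a = seq_len(n), b = seq_len(n))
  .cubecat$weights <- matrix(pair_weight(idx$a, idx$b), n, n)
  .cubecat$weights
}

#' Weighted entropy of a co-occurrence matrix (bits)
#'
#' `H_w = -sum_ij w[i,j] * p[i,j] * log2(p[i,j])` with
#' `p = f / sum(f)` and zero cells contributing nothing. An all-zero matrix
#' yields 0 with a warning.
#'
#' @param f Nonnegative count matrix (e.g. from [build_cooccurrence()]).
#' @param weights Weight matrix conformable with `f`
#'   (default [shape_pair_weights()]).
#' @return Weighted entropy in bits.
#' @export
weighted_entropy <- function(f, weights = shape_pair_weights()) {
  stopifnot(all(dim(f) == dim(weights)))
  total <- sum(f)
  if (total == 0) {
    warning("all-zero co-occurrence matrix; weighted entropy is 0", call. = FALSE)
    return(0)
  }
  nz <- f > 0
  p <- f[nz] / total
  -sum(weights[nz] * p * log2(p))
}

#' Configurational complexity (bits)
#'
#' Disorder of the arrangement, measured as weighted entropy of adjacent-pair
#' co-occurrence counts. Assembly and Spatial-Memory pool all four directions
#' (0, 45, 90, 135 degrees, circulant) into one matrix; Sequence-Memory uses
#' the 0-degree pairs along the sequence with circulant closure;
#' Shape-Matching sums the weighted entropies of three separate matrices —
#' horizontal (0), vertical (90), and diagonal (45 + 135) — over the full
#' pattern. Items with no adjacent pair (e.g. a length-1 sequence) score 0.
#'
#' @param item A [grid_item()], [shape_matching_item()] or [sequence_item()].
#' @param params [complexity_params()] (unused by the entropy itself; kept so
#'   all complexity operations share one signature).
#' @return Configurational complexity in bits.
#' @export
configurational_complexity <- function(item, params = complexity_params()) {
  if (inherits(item, "sequence_item")) {
    if (length(item$shapes) < 2L) return(0)
    f <- build_cooccurrence(matrix(item$shapes, nrow = 1L), "0", circulant = TRUE)
    return(weighted_entropy(f))
  }
  grid <- if (inherits(item, "shape_matching_item")) item$base else item
  stopifnot(inherits(grid, "grid_item"))
  if (grid$game == "shape_matching") {
    fs <- list(
      build_cooccurrence(grid, "0"),
      build_cooccurrence(grid, "90"),
      build_cooccurrence(grid, c("45", "135"))
    )
    return(sum(vapply(fs, weighted_entropy, numeric(1))))
  }
  weighted_entropy(build_cooccurrence(grid, pair_directions, circulant = TRUE))
}

# ---- play complexity ---------------------------------------------------------

complexity_breakdown <- function(game, c_play, c_compos = NA_real_,
                                 c_config = NA_real_, k = NA_real_,
                                 c_m = NA_real_, c_s = NA_real_, c_l = NA_real_) {
  structure(list(game = game, c_compos = c_compos, c_config = c_config,
                 k = k, c_play = c_play, c_m = c_m, c_s = c_s, c_l = c_l),
            class = "complexity_breakdown")
}

#' @export
print.complexity_breakdown <- function(x, ...) {
  cat(sprintf("<complexity_breakdown: %s, C_play = %.4f>\n", x$game, x$c_play))
  terms <- unlist(x[c("c_compos", "c_config", "k", "c_m", "c_s", "c_l")])
  terms <- terms[!is.na(terms)]
  if (length(terms)) {
    cat(paste(sprintf("  %-8s %.4f", names(terms), terms), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Play complexity of a game item
#'
#' The scalar difficulty estimate driving item generation and the adaptive
#' engine. For Assembly, Spatial-Memory and Sequence-Memory,
#' `C_play = k(C_config) * C_compos + C_config`, where the sigmoid gate
#' `k(x) = 1 / (1 + exp(-alpha (x - beta)))` suppresses the compositional
#' term when the arrangement is orderly: an item formed only by identical
#' triangles has a large `C_compos` but `C_config = 0`, so `C_play` stays
#' small. Shape-Matching uses `C_play = C_config` alone (more shapes in the
#' pattern do not necessarily make completing it harder). Path-Tracking uses
#' the network complexity of the path graph ([path_network_complexity()]) and
#' Maze the composed maze measure ([maze_play_complexity()]).
#'
#' @param item A game item.
#' @param params [complexity_params()].
#' @return A `complexity_breakdown` with fields `c_compos`, `c_config`, `k`,
#'   `c_play` (and `c_m`, `c_s`, `c_l` for mazes).
#' @export
#' @examples
#' play_complexity(grid_item(matrix(c(1, 8, 2, 7), 2, 2), "assembly"))
play_complexity <- function(item, params = complexity_params()) {
  UseMethod("play_complexity")
}

#' @export
play_complexity.default <- function(item, params = complexity_params()) {
  stop("no play-complexity measure for objects of class ",
       paste(class(item), collapse = "/"), call. = FALSE)
}

compose_play <- function(game, item, params) {
  c_compos <- compositional_complexity(item, params)
  c_config <- configurational_complexity(item, params)
  k <- sigmoid_k(c_config, params)
  complexity_breakdown(game, c_play = k * c_compos + c_config,
                       c_compos = c_compos, c_config = c_config, k = k)
}

#' @export
play_complexity.grid_item <- function(item, params = complexity_params()) {
  if (item$game == "shape_matching") {
    c_config <- configurational_complexity(item, params)
    return(complexity_breakdown("shape_matching", c_play = c_config,
                                c_config = c_config,
                                c_compos = compositional_complexity(item, params)))
  }
  compose_play(item$game, item, params)
}

#' @export
play_complexity.shape_matching_item <- function(item, params = complexity_params()) {
  play_complexity(item$base, params)
}

#' @export
play_complexity.sequence_item <- function(item, params = complexity_params()) {
  compose_play("sequence_memory", item, params)
}

#' @export
play_complexity.path_item <- function(item, params = complexity_params()) {
  complexity_breakdown("path_tracking", c_play = path_network_complexity(item))
}

#' @export
play_complexity.maze_item <- function(item, params = complexity_params()) {
  maze_play_complexity(item, params)
}
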