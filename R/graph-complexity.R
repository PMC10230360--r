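#' Entropy of a normalised vertex-degree distribution (bits)
#'
#' The network complexity used by Path-Tracking and the maze term `C_m`:
#' degrees `a_i` over `V` vertices are normalised to `p_i = a_i / sum(a)` and
#' their Shannon entropy taken. All-equal degrees give `log2(V)`; dispersion
#' in the degrees moves the value away from that uniform ceiling.
#'
#' @param degrees Positive integer vertex degrees, length >= 2.
#' @return Entropy in bits.
#' @export
#' @examples
#' degree_entropy(c(1, 1))     # 1 bit
#' degree_entropy(rep(2, 8))   # log2(8) = 3 bits
degree_entropy <- function(degrees) {
  if (length(degrees) < 2L) stop("need at least 2 vertices", call. = FALSE)
  if (any(degrees <= 0)) stop("degrees must be positive", call. = FALSE)
  shannon_entropy(degrees / sum(degrees))
}

#' Network complexity of a Path-Tracking item
#'
#' Entropy of the normalised degree distribution of the path graph (endpoints
#' have degree 1, interior nodes degree 2).
#'
#' @param path A [path_item()].
#' @return Network complexity in bits.
#' @export
path_network_complexity <- function(path) {
  stopifnot(inherits(path, "path_item"))
  degree_entropy(path$degrees)
}

# neighbours of 1-based cell (i, j) across open walls; returns matrix rows (i, j)
maze_neighbours <- function(maze, i, j) {
  dim <- maze$dim
  out <- matrix(integer(), ncol = 2L)
  if (j < dim && maze$open_right[i, j]) out <- rbind(out, c(i, j + 1L))
  if (j > 1L && maze$open_right[i, j - 1L]) out <- rbind(out, c(i, j - 1L))
  if (i < dim && maze$open_down[i, j]) out <- rbind(out, c(i + 1L, j))
  if (i > 1L && maze$open_down[i - 1L, j]) out <- rbind(out, c(i - 1L, j))
  out
}

#' Vertex degrees of the maze cell graph
#'
#' @param maze A [maze_item()].
#' @return A `dim x dim` integer matrix of open-passage counts per cell.
#' @export
maze_degrees <- function(maze) {
  stopifnot(inherits(maze, "maze_item"))
  d <- maze$dim
  deg <- matrix(0L, d, d)
  right <- maze$open_right; right[, d] <- FALSE
  down <- maze$open_down; down[d, ] <- FALSE
  deg <- deg + right                              # passage to the right
  deg[, -1L] <- deg[, -1L] + right[, -d]          # passage to the left
  deg <- deg + down                               # passage below
  deg[-1L, ] <- deg[-1L, ] + down[-d, ]           # passage above
  deg
}

#' Solve a maze with A* search
#'
#' Best-first search with the Manhattan-distance heuristic over the maze cell
#' graph. Returns the maze with its solution slot filled: the minimal-length
#' cell sequence from start to end, its length `L` (cells, both endpoints
#' included; `L = 1` when start equals end) and the maze-graph degree `s_i`
#' of each solution cell.
#'
#' @param maze A [maze_item()].
#' @return The solved `maze_item` (fields `solution`, `L`,
#'   `solution_degrees` set).
#' @export
astar_shortest <- function(maze) {
  stopifnot(inherits(maze, "maze_item"))
  d <- maze$dim
  sI <- maze$start + 1L; eI <- maze$end + 1L
  idx <- function(i, j) (j - 1L) * d + i
  n <- d * d
  g <- rep(Inf, n)            # cost from start (cells counted from 0)
  fsc <- rep(Inf, n)          # g + heuristic
  parent <- rep(NA_integer_, n)
  open <- rep(FALSE, n)
  closed <- rep(FALSE, n)
  s <- idx(sI[1], sI[2]); e <- idx(eI[1], eI[2])
  h <- function(k) {
    i <- ((k - 1L) %% d) + 1L; j <- ((k - 1L) %/% d) + 1L
    abs(i - eI[1]) + abs(j - eI[2])
  }
  g[s] <- 0; fsc[s] <- h(s); open[s] <- TRUE
  found <- FALSE
  while (any(open)) {
    cur <- which(open)[which.min(fsc[open])]
    if (cur == e) { found <- TRUE; break }
    open[cur] <- FALSE; closed[cur] <- TRUE
    ci <- ((cur - 1L) %% d) + 1L; cj <- ((cur - 1L) %/% d) + 1L
    nbrs <- maze_neighbours(maze, ci, cj)
    for (r in seq_len(nrow(nbrs))) {
      k <- idx(nbrs[r, 1], nbrs[r, 2])
      if (closed[k]) next
      tentative <- g[cur] + 1
      if (tentative < g[k]) {
        g[k] <- tentative
        fsc[k] <- tentative + h(k)
        parent[k] <- cur
        open[k] <- TRUE
      }
    }
  }
  if (!found) {
    stop(structure(class = c("cubecat_no_path", "error", "condition"),
                   list(message = "maze end is not reachable from start",
                        call = sys.call())))
  }
  cells <- integer()
  k <- e
  while (!is.na(k)) { cells <- c(k, cells); k <- parent[k] }
  sol <- cbind(((cells - 1L) %% d), ((cells - 1L) %/% d))  # back to 0-based (row, col)
  deg <- maze_degrees(maze)
  maze$solution <- sol
  maze$L <- nrow(sol)
  maze$solution_degrees <- deg[cells]
  maze
}

#' Play complexity of a maze item
#'
#' Composes three terms: `C_m`, the network complexity of the whole maze cell
#' graph (entropy of its normalised degree distribution); `C_s`, the solution
#' logarithmic complexity `mean(log2(s_i))` over the `L` cells of the A*
#' shortest path, capturing the vertex degrees met along the solution; and
#' `C_l = log2(L)`, capturing the solution length. These are combined as
#' `C_play = 0.4 * (C_m + 10 * (C_s + C_l))`: the factor 10 balances the
#' solution terms against the range of `C_m`, and 0.4 brings the result onto
#' a scale comparable with the other games.
#'
#' @param maze A [maze_item()] (solved or not; A* is run if needed).
#' @param params [complexity_params()].
#' @return A `complexity_breakdown` with `c_m`, `c_s`, `c_l` and `c_play`.
#' @export
maze_play_complexity <- function(maze, params = complexity_params()) {
  stopifnot(inherits(maze, "maze_item"))
  if (is.null(maze$solution)) maze <- astar_shortest(maze)
  c_m <- degree_entropy(as.vector(maze_degrees(maze)))
  c_s <- mean(log2(maze$solution_degrees))
  c_l <- log2(maze$L)
  c_play <- params$maze_scale * (c_m + params$maze_inner_scale * (c_s + c_l))
  complexity_breakdown("maze", c_play = c_play, c_m = c_m, c_s = c_s, c_l = c_l)
}
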