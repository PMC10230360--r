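# Independent oracles used across the suite. These deliberately re-derive
# quantities with different algorithms/data structures than the package.

# distinct appearances of a glyph mask under quarter-turn rotation, computed
# by literally rotating the rendered mask and deduplicating
oracle_mask_fold <- function(mask) {
  rot <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  seen <- character()
  cur <- mask
  for (i in 1:4) {
    seen <- union(seen, paste(cur, collapse = "/"))
    cur <- rot(cur)
  }
  length(seen)
}

oracle_glyphs <- list(
  square = matrix(1L, 4, 4),
  strip = {
    m <- matrix(0L, 4, 4); m[, 2:3] <- 1L; m
  },
  triangle = {
    m <- matrix(0L, 4, 4); m[lower.tri(m, diag = TRUE)] <- 1L; m
  }
)

# ordered adjacent pairs by explicit per-direction looping (wrap via modular
# index arithmetic), written independently of the package's line walker
oracle_pairs <- function(m, direction, circulant = TRUE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(integer(), ncol = 2L)
  add <- function(a, b) out <<- rbind(out, c(a, b))
  emit_line <- function(cells) {
    len <- length(cells)
    if (len < 2L) return()
    for (i in 1:(len - 1L)) add(cells[i], cells[i + 1L])
    if (circulant) add(cells[len], cells[1L])
  }
  if (direction == "0") {
    for (i in 1:nr) emit_line(m[i, ])
  } else if (direction == "90") {
    for (j in 1:nc) emit_line(m[, j])
  } else if (direction == "45") {
    # up-right anti-diagonals, ordered from the bottom-left cell
    for (s in 2:(nr + nc)) {
      is <- seq(min(nr, s - 1L), max(1L, s - nc))
      cells <- vapply(is, function(i) m[i, s - i], m[1, 1])
      emit_line(cells)
    }
  } else if (direction == "135") {
    # up-left diagonals, ordered from the bottom-right cell
    for (d in (1L - nc):(nr - 1L)) {
      is <- seq(min(nr, nc + d), max(1L, 1L + d))
      cells <- vapply(is, function(i) m[i, i - d], m[1, 1])
      emit_line(cells)
    }
  } else {
    stop("bad direction in oracle")
  }
  out
}

# dictionary-style co-occurrence count over a set of directions
oracle_cooccurrence <- function(m, directions, circulant = TRUE, n = 14L) {
  f <- matrix(0L, n, n)
  for (d in directions) {
    pr <- oracle_pairs(m, d, circulant)
    for (r in seq_len(nrow(pr))) {
      f[pr[r, 1], pr[r, 2]] <- f[pr[r, 1], pr[r, 2]] + 1L
    }
  }
  f
}

# plain breadth-first search over the maze cell graph; returns the number of
# cells on a shortest start-end path
oracle_bfs_length <- function(maze) {
  d <- maze$dim
  dist <- matrix(NA_integer_, d, d)
  q <- list(maze$start + 1L)
  dist[q[[1]][1], q[[1]][2]] <- 1L
  while (length(q)) {
    cell <- q[[1]]; q <- q[-1]
    i <- cell[1]; j <- cell[2]
    step <- function(ni, nj) {
      if (is.na(dist[ni, nj])) {
        dist[ni, nj] <<- dist[i, j] + 1L
        q[[length(q) + 1L]] <<- c(ni, nj)
      }
    }
    if (j < d && maze$open_right[i, j]) step(i, j + 1L)
    if (j > 1L && maze$open_right[i, j - 1L]) step(i, j - 1L)
    if (i < d && maze$open_down[i, j]) step(i + 1L, j)
    if (i > 1L && maze$open_down[i - 1L, j]) step(i - 1L, j)
  }
  dist[maze$end[1] + 1L, maze$end[2] + 1L]
}

# Spearman correlation from first principles: average ranks, Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# default test bands / configs shared across files
maze_adaptive_config <- function() {
  adaptive_config(start_c = 15, ceiling_c = 25, up_step = 0.5,
                  min_step = 0.05, max_items = 25L)
}
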