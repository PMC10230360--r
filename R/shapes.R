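#' cubecat: entropy-based play complexity and adaptive block-game assessment
#'
#' Computational core of a six-game cube-based cognitive assessment battery:
#' play-complexity measures, target-complexity item generators, a rule-based
#' dynamic-difficulty engine, scoring, and simulated examinees.
#'
#' @keywords internal
"_PACKAGE"

# package-local cache (taxonomy, pair-index memoisation)
.cubecat <- new.env(parent = emptyenv())

#' Binary glyph mask for a cube-face geometry
#'
#' Each cube face shows a black-and-white glyph: a full square, a stripe, or a
#' half-square triangle. The mask is an 8x8 0/1 matrix; its behaviour under
#' 90-degree rotation determines how many distinct appearances the face has.
#'
#' @param geometry `"square"`, `"strip"`, or `"triangle"`.
#' @return An 8x8 integer matrix of 0/1.
#' @keywords internal
shape_glyph <- function(geometry) {
  n <- 8L
  m <- matrix(0L, n, n)
  switch(geometry,
    square = m[] <- 1L,
    strip = m[, (n / 2):(n / 2 + 1L)] <- 1L,
    triangle = m[lower.tri(m, diag = TRUE)] <- 1L,
    stop("unknown geometry: ", geometry)
  )
  m
}

# rotate a matrix a quarter turn clockwise
rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

#' Rotational symmetry fold of a glyph
#'
#' Number of distinct appearances of the glyph under rotations by 0, 90, 180
#' and 270 degrees (1 for squares, 2 for strips, 4 for triangles).
#'
#' @param geometry `"square"`, `"strip"`, or `"triangle"`.
#' @return Integer fold in `{1, 2, 4}`.
#' @export
#' @examples
#' shape_fold("strip")
shape_fold <- function(geometry) {
  key <- paste0("fold.", geometry)
  if (!is.null(.cubecat[[key]])) return(.cubecat[[key]])
  m <- shape_glyph(geometry)
  seen <- character()
  cur <- m
  for (i in 1:4) {
    seen <- union(seen, paste(cur, collapse = ""))
    cur <- rot90cw(cur)
  }
  .cubecat[[key]] <- length(seen)
  .cubecat[[key]]
}

#' Enumerate the distinct cube-face appearances
#'
#' The six faces of a cube carry two colour roles (A = black-on-white,
#' B = white-on-black) of each of three glyphs (square, strip, triangle).
#' Rotating every face by 0, 90, 180 and 270 degrees and removing duplicates
#' yields the taxonomy of distinct surface appearances; each appearance gets a
#' stable integer id. Ids are ordered square < strip < triangle, colour A < B,
#' orientation ascending.
#'
#' @return A data frame with columns `id`, `geometry`, `color`, `orientation`
#'   (quarter turns, `0 <= orientation < fold`) and `fold`.
#' @export
#' @examples
#' nrow(surface_shapes())
surface_shapes <- function() {
  if (!is.null(.cubecat$taxonomy)) return(.cubecat$taxonomy)
  geoms <- c("square", "strip", "triangle")
  rows <- list()
  for (g in geoms) {
    fold <- shape_fold(g)
    for (col in c("A", "B")) {
      # all 4 quarter-turn appearances, deduplicated by the glyph's symmetry
      orientations <- unique((0:3) %% fold)
      rows[[length(rows) + 1L]] <- data.frame(
        geometry = g, color = col, orientation = sort(orientations),
        fold = fold, stringsAsFactors = FALSE
      )
    }
  }
  tax <- do.call(rbind, rows)
  tax <- tax[order(match(tax$geometry, geoms), tax$color, tax$orientation), ]
  tax$id <- seq_len(nrow(tax))
  tax <- tax[, c("id", "geometry", "color", "orientation", "fold")]
  rownames(tax) <- NULL
  .cubecat$taxonomy <- tax
  tax
}

n_shapes <- function() nrow(surface_shapes())

assert_shape_id <- function(id) {
  tax <- surface_shapes()
  bad <- !(id %in% tax$id)
  if (any(bad)) {
    stop("unknown surface shape id: ", paste(unique(id[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(id)
}

#' Rotate a surface shape by quarter turns
#'
#' Returns the id of the appearance obtained by rotating the given shape
#' clockwise by `quarter_turns` 90-degree steps. Rotation by the shape's fold
#' (and hence by 4) is the identity.
#'
#' @param id A valid surface-shape id (see [surface_shapes()]).
#' @param quarter_turns Integer number of 90-degree turns (may be negative).
#' @return The rotated shape id (vectorised over `id`).
#' @export
#' @examples
#' rotate_shape(1, 1)  # squares are rotation-invariant
rotate_shape <- function(id, quarter_turns) {
  assert_shape_id(id)
  stopifnot(is.numeric(quarter_turns), length(quarter_turns) == 1L,
            quarter_turns == round(quarter_turns))
  tax <- surface_shapes()
  row <- tax[match(id, tax$id), ]
  new_orient <- (row$orientation + as.integer(quarter_turns)) %% row$fold
  key <- paste(tax$geometry, tax$color, tax$orientation)
  tax$id[match(paste(row$geometry, row$color, new_orient), key)]
}
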