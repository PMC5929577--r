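# Grid geometry: coordinates are 0-based (x, y) with y increasing Northward.
# Cells are linear indices 1..width*height with x varying fastest.

#' Cardinal movements
#'
#' The four unit displacements of the known spatial kernel, in the fixed
#' order North, South, East, West. North is (0, 1): y increases Northward.
#'
#' @format A 4x2 integer matrix with rownames North/South/East/West and
#'   columns `dx`, `dy`.
#' @export
cardinal_movements <- function() {
  m <- rbind(North = c(0L, 1L), South = c(0L, -1L),
             East  = c(1L, 0L), West  = c(-1L, 0L))
  colnames(m) <- c("dx", "dy")
  m
}

MOVEMENT_NAMES <- c("North", "South", "East", "West")
N_ACTIONS <- 8L

#' Construct a grid specification
#'
#' @param width,height Grid dimensions in cells (each at least 2).
#' @return An object of class `grid_spec` with fields `width`, `height`,
#'   `n_cells`, and a precomputed successor table `succ` (`n_cells` x 4
#'   integer matrix, columns in movement order North/South/East/West) giving
#'   the cell reached from each cell by each movement, with per-axis
#'   clamping at the walls.
#' @export
grid_spec <- function(width, height) {
  width <- as.integer(width)
  height <- as.integer(height)
  stopifnot(width >= 2L, height >= 2L)
  n <- width * height
  xy <- cell_to_xy(seq_len(n), width)
  mv <- cardinal_movements()
  succ <- matrix(0L, n, 4L, dimnames = list(NULL, MOVEMENT_NAMES))
  for (j in 1:4) {
    nx <- pmin(pmax(xy[, 1] + mv[j, 1], 0L), width - 1L)
    ny <- pmin(pmax(xy[, 2] + mv[j, 2], 0L), height - 1L)
    succ[, j] <- xy_to_cell(nx, ny, width)
  }
  structure(list(width = width, height = height, n_cells = n, succ = succ),
            class = "grid_spec")
}

#' Convert between cell indices and 0-based coordinates
#'
#' @param cell Integer cell index in 1..width*height.
#' @param width Grid width.
#' @return For `cell_to_xy`, an n x 2 integer matrix of (x, y); for
#'   `xy_to_cell`, an integer vector of cell indices.
#' @export
cell_to_xy <- function(cell, width) {
  cell <- as.integer(cell) - 1L
  cbind(x = cell %% width, y = cell %/% width)
}

#' @rdname cell_to_xy
#' @param x,y 0-based coordinates.
#' @export
xy_to_cell <- function(x, y, width) {
  as.integer(y) * as.integer(width) + as.integer(x) + 1L
}

# Manhattan distance between two cells of a grid.
manhattan <- function(cell_a, cell_b, width) {
  a <- cell_to_xy(cell_a, width)
  b <- cell_to_xy(cell_b, width)
  unname(abs(a[, 1] - b[, 1]) + abs(a[, 2] - b[, 2]))
}
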