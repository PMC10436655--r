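#' Gridded population counts
#'
#' A regular north-up grid of nonnegative person counts. `values` is a
#' matrix with `nrow` rows (y, row 1 = northernmost) and `ncol` columns
#' (x); `origin` is the lower-left corner of the grid in planar meters.
#'
#' @param origin Numeric `c(x, y)`: lower-left corner.
#' @param cell_size Cell edge, meters.
#' @param values Matrix of nonnegative finite counts.
#' @return An object of class `pop_grid`.
#' @export
pop_grid <- function(origin, cell_size, values) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid values must be finite and nonnegative")
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 values = values), class = "pop_grid")
}

#' @export
print.pop_grid <- function(x, ...) {
  cat(sprintf("<pop_grid: %d x %d cells of %gm, origin (%g, %g), total %g>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(x$values)))
  invisible(x)
}

#' Cell centers of a population grid
#' @param grid A `pop_grid`.
#' @return data.frame with `row`, `col`, `x`, `y` for every cell.
#' @export
grid_centers <- function(grid) {
  ny <- nrow(grid$values); nx <- ncol(grid$values)
  col <- rep(seq_len(nx), each = ny)
  row <- rep(seq_len(ny), times = nx)
  data.frame(
    row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (ny - row + 0.5) * grid$cell_size)
}

#' Total population of a grid
#' @param grid A `pop_grid`.
#' @export
grid_total <- function(grid) sum(grid$values)
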