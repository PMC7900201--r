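#' Regular raster grid specification
#'
#' Defines the prediction grid used throughout the package: a regular raster
#' of square cells in projected metric coordinates, origin at the lower-left
#' corner, cell-centre registration, half-open extents. The default is the
#' 20 x 20 grid of 250-m cells (6.25 ha pixels, 2500 ha = 25 km^2 in total)
#' over which fruit-fall is interpolated.
#'
#' @param origin_x,origin_y Projected coordinates (m) of the lower-left
#'   corner of the grid.
#' @param n_rows,n_cols Number of cells in the y and x directions.
#' @param cell_size Cell edge length in metres (default 250).
#'
#' @return An object of class `grid_spec`: a list with the arguments plus
#'   `pixel_area_ha` (cell_size^2 / 1e4), `extent_x`/`extent_y` (m) and
#'   `total_area_ha`.
#' @export
#' @examples
#' g <- grid_spec()
#' g$total_area_ha  # 2500
grid_spec <- function(origin_x = 0, origin_y = 0, n_rows = 20, n_cols = 20,
                      cell_size = 250) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop("grid must have at least one cell in each direction", call. = FALSE)
  g <- list(
    origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
    n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
    pixel_area_ha = cell_size^2 / 1e4,
    extent_x = n_cols * cell_size, extent_y = n_rows * cell_size,
    total_area_ha = n_rows * n_cols * cell_size^2 / 1e4
  )
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m (%g ha/pixel, %g ha total)\n",
              x$n_rows, x$n_cols, x$cell_size, x$pixel_area_ha,
              x$total_area_ha))
  cat(sprintf("  origin (%g, %g), extent %g x %g m\n",
              x$origin_x, x$origin_y, x$extent_x, x$extent_y))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A data.frame with one row per cell in column-major matrix order
#'   (the order of `as.vector()` on a layer matrix), columns `row`, `col`,
#'   `x`, `y`.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  data.frame(
    row = rows, col = cols,
    x = grid$origin_x + (cols - 0.5) * grid$cell_size,
    y = grid$origin_y + (rows - 0.5) * grid$cell_size
  )
}

#' Map points to grid cells
#'
#' Cells are half-open: a point on the shared edge of two cells belongs to
#' the cell with the larger index.
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates (m), recycled to common length.
#' @return A data.frame with columns `row`, `col` (1-based matrix indices).
#' @export
point_to_cell <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the grid extent", sum(bad)),
         call. = FALSE)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Environmental covariate raster stack
#'
#' Bundles the continuous covariate layers and the categorical basin raster
#' on a common grid. Layer matrices are indexed `[row, col]` with row 1 the
#' southernmost row (y increases with row index).
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices, all `n_rows x n_cols`.
#' @param basin Integer matrix of watershed ids, same dimensions.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, layers, basin) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers))
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named", call. = FALSE)
  dims <- c(grid$n_rows, grid$n_cols)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || !all(dim(m) == dims))
      stop(sprintf("layer '%s' does not match the grid dimensions", nm),
           call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("layer '%s' contains non-finite values", nm), call. = FALSE)
  }
  if (!is.matrix(basin) || !all(dim(basin) == dims))
    stop("basin raster does not match the grid dimensions", call. = FALSE)
  structure(list(grid = grid, layers = layers,
                 basin = matrix(as.integer(basin), nrow = dims[1])),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d layers + basin on a %d x %d grid\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  basins: %d\n", length(unique(as.vector(x$basin)))))
  invisible(x)
}

#' Extract covariate values at point locations
#'
#' Nearest-pixel (containing-cell) lookup of every layer plus the basin id.
#'
#' @param stack A [covariate_stack()].
#' @param x,y Point coordinates (m).
#' @return A data.frame, one row per point, one column per layer plus
#'   `Basin` (factor).
#' @export
extract_at_points <- function(stack, x, y) {
  stopifnot(inherits(stack, "covariate_stack"))
  rc <- point_to_cell(stack$grid, x, y)
  idx <- cbind(rc$row, rc$col)
  out <- lapply(stack$layers, function(m) m[idx])
  out$Basin <- factor(stack$basin[idx])
  as.data.frame(out, optional = TRUE)
}

#' Flatten a stack to a per-pixel data.frame
#'
#' @param stack A [covariate_stack()].
#' @return A data.frame, one row per pixel in column-major matrix order, with
#'   all layers, `Basin` (factor), and cell-centre `Longitude` (x) and
#'   `Latitude` (y) in metres.
#' @export
stack_as_table <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  cc <- cell_centers(stack$grid)
  out <- lapply(stack$layers, as.vector)
  out$Basin <- factor(as.vector(stack$basin))
  out <- as.data.frame(out, optional = TRUE)
  out$Longitude <- cc$x
  out$Latitude <- cc$y
  out
}
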