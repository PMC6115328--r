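#' Analysis grid specification
#'
#' A `grid_spec` describes a regular geographic grid in WGS84 decimal
#' degrees: cell-edge registered, row-major from the north-west corner.
#' Cell `(r, c)` covers the half-open intervals
#' `[xmin + (c-1)*res, xmin + c*res)` in longitude and, going downward from
#' the top edge, `(ymax - r*res, ymax - (r-1)*res]` in latitude, so a point
#' exactly on an interior horizontal edge belongs to the cell below it and a
#' point on an interior vertical edge to the cell to its east.
#'
#' The default resolution, 2.5 arc-minutes (0.0416667 degrees, roughly 4.6 km
#' at the equator), stands in for a nominal 5 x 5 km analysis cell.
#'
#' @param xmin Longitude of the grid's west edge (decimal degrees).
#' @param ymax Latitude of the grid's north edge (decimal degrees).
#' @param res Cell size in decimal degrees; must be positive.
#' @param nrow,ncol Grid extent in cells; must be positive integers.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(xmin = 0, ymax = 10, res = 1, nrow = 10, ncol = 10)
#' cell_at(g, x = 0.5, y = 9.5) # row 1, col 1
#' @export
grid_spec <- function(xmin, ymax, res = 1 / 24, nrow, ncol) {
  stopifnot(is.numeric(xmin), is.numeric(ymax), res > 0, nrow >= 1, ncol >= 1)
  structure(
    list(xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         res = as.numeric(res), nrow = as.integer(nrow), ncol = as.integer(ncol)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, res %g deg, x [%g, %g], y [%g, %g]\n",
              x$nrow, x$ncol, x$res,
              x$xmin, x$xmin + x$ncol * x$res,
              x$ymax - x$nrow * x$res, x$ymax))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%g(%g,%g)", x$nrow, x$ncol, x$res, x$xmin, x$ymax)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$res - b$res) < tol
}

#' Stop unless two layers share one grid
#'
#' All overlay arithmetic in the pipeline requires layers on an identical
#' grid; any mismatch is a hard error (never a silent resample).
#'
#' @param a,b Objects carrying a `$grid` (or `grid_spec`s).
#' @param what_a,what_b Labels used in the error message.
#' @return Invisibly `TRUE`.
#' @export
check_same_grid <- function(a, b, what_a = "first layer", what_b = "second layer") {
  ga <- if (inherits(a, "grid_spec")) a else a$grid
  gb <- if (inherits(b, "grid_spec")) b else b$grid
  if (!grids_identical(ga, gb)) {
    abort(sprintf("grid mismatch: %s is %s but %s is %s",
                  what_a, format(ga), what_b, format(gb)))
  }
  invisible(TRUE)
}

#' Locate grid cells containing points
#'
#' @param grid A `grid_spec`.
#' @param x,y Point coordinates (decimal degrees), recycled to equal length.
#' @return A tibble with columns `row`, `col` (NA for points outside the
#'   grid extent).
#' @export
cell_at <- function(grid, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  col <- floor((x - grid$xmin) / grid$res) + 1L
  row <- floor((grid$ymax - y) / grid$res) + 1L
  # top edge belongs to row 1, west edge to col 1 (half-open convention)
  row[y == grid$ymax] <- 1L
  ok <- row >= 1L & row <= grid$nrow & col >= 1L & col <= grid$ncol
  row[!ok] <- NA_integer_; col[!ok] <- NA_integer_
  tibble(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @param grid A `grid_spec`.
#' @param row,col Cell indices (1-based), recycled to equal length. Defaults
#'   to every cell in row-major order.
#' @return A tibble with columns `row`, `col`, `x`, `y`.
#' @export
cell_centres <- function(grid, row = NULL, col = NULL) {
  if (is.null(row)) {
    row <- rep(seq_len(grid$nrow), each = grid$ncol)
    col <- rep(seq_len(grid$ncol), times = grid$nrow)
  }
  n <- max(length(row), length(col))
  row <- rep_len(as.integer(row), n); col <- rep_len(as.integer(col), n)
  tibble(row = row, col = col,
         x = grid$xmin + (col - 0.5) * grid$res,
         y = grid$ymax - (row - 0.5) * grid$res)
}

#' Gridded raster layer
#'
#' A `grid_raster` couples a [grid_spec()] with a matrix of per-cell values
#' (`NA` encodes nodata). Values may be numeric, integer or logical.
#'
#' @param grid A `grid_spec`.
#' @param values A matrix of dimension `nrow x ncol`, or a single value to
#'   fill with.
#' @param name Optional layer name (used in printing and plots).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(grid, values = NA_real_, name = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values)) {
    values <- matrix(values, nrow = grid$nrow, ncol = grid$ncol)
  }
  if (nrow(values) != grid$nrow || ncol(values) != grid$ncol) {
    abort("values matrix does not match the grid extent")
  }
  structure(list(grid = grid, values = values, name = name),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<grid_raster%s> %d x %d, res %g deg, values [%g, %g], %d nodata\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$grid$nrow, x$grid$ncol, x$grid$res,
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @describeIn grid_raster Long tidy view: one row per cell with centre
#'   coordinates and value.
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @export
as_tibble.grid_raster <- function(x, ...) {
  cc <- cell_centres(x$grid)
  cc$value <- as.vector(t(x$values))
  cc
}

#' Look up raster values at point locations
#'
#' @param raster A `grid_raster`.
#' @param x,y Coordinates in decimal degrees.
#' @return Vector of cell values (`NA` for points off the grid or nodata
#'   cells).
#' @export
raster_value_at <- function(raster, x, y) {
  rc <- cell_at(raster$grid, x, y)
  ok <- !is.na(rc$row)
  out <- vector(mode = typeof(raster$values), length = nrow(rc))
  out[] <- NA
  out[ok] <- raster$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = object$name %||% "value") +
    ggplot2::theme_minimal()
}
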