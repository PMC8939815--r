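#' Construct a single-date raster grid
#'
#' An `ndvi_grid` is the package's core raster container: a numeric matrix of
#' index values on a square-pixel grid, with `NA` marking cells where no
#' observation exists. Row 1 is the northern edge of the raster; map `x`
#' increases eastward and `y` northward. `origin` is the map coordinate of the
#' outer (north-west) corner of the cell in row 1, column 1.
#'
#' Valid values are required to lie inside `range` (default `[0, 1]`, the NDVI
#' convention used throughout). Values overshooting the range by at most
#' `clamp_tol` (compression/resampling artifacts) are clamped into the range
#' with a warning; larger excursions are an error. Pass `range = NULL` for
#' unbounded derived grids such as seasonal NDVI sums.
#'
#' @param values numeric matrix; `NA` encodes missing cells.
#' @param pixel_size side length of the (square) pixels in metres.
#' @param origin length-2 numeric, map coordinates (x, y) of the north-west
#'   corner of the grid.
#' @param date observation date as an ordinal day number (or `NA`).
#' @param range permitted closed interval for valid values, or `NULL` for none.
#' @param clamp_tol tolerance beyond `range` that is clamped rather than
#'   rejected.
#' @return an object of class `ndvi_grid`.
#' @export
ndvi_grid <- function(values, pixel_size, origin = c(0, 0), date = NA_real_,
                      range = c(0, 1), clamp_tol = 0.01) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive finite number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite map coordinates")
  if (!is.null(range)) {
    v <- values[!is.na(values)]
    if (any(v < range[1] - clamp_tol | v > range[2] + clamp_tol))
      stop(sprintf("valid values outside [%g, %g] beyond tolerance %g",
                   range[1], range[2], clamp_tol))
    if (any(v < range[1] | v > range[2])) {
      warning(sprintf("%d value(s) clamped into [%g, %g]",
                      sum(v < range[1] | v > range[2]), range[1], range[2]))
      values[] <- pmin(pmax(values, range[1]), range[2])
    }
  }
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), date = as.numeric(date), range = range),
    class = "ndvi_grid"
  )
}

#' @export
dim.ndvi_grid <- function(x) dim(x$values)

#' Logical mask of observed cells
#' @param grid an `ndvi_grid`.
#' @return logical matrix, `TRUE` where an observation is present.
#' @export
valid_mask <- function(grid) !is.na(grid$values)

#' Vector of observed cell values
#' @param grid an `ndvi_grid`.
#' @return numeric vector of the valid cells (column-major order).
#' @export
grid_values <- function(grid) grid$values[!is.na(grid$values)]

#' Map-coordinate extent of a grid
#' @param grid an `ndvi_grid`.
#' @return named numeric `c(xmin, xmax, ymin, ymax)`; half-open cell convention.
#' @export
grid_extent <- function(grid) {
  d <- dim(grid$values); ps <- grid$pixel_size
  c(xmin = grid$origin[1], xmax = grid$origin[1] + d[2] * ps,
    ymin = grid$origin[2] - d[1] * ps, ymax = grid$origin[2])
}

#' Map coordinates of pixel centers
#' @param grid an `ndvi_grid`.
#' @return list with `x` (per column) and `y` (per row) center coordinates.
#' @export
pixel_centers <- function(grid) {
  d <- dim(grid$values); ps <- grid$pixel_size
  list(x = grid$origin[1] + (seq_len(d[2]) - 0.5) * ps,
       y = grid$origin[2] - (seq_len(d[1]) - 0.5) * ps)
}

#' @export
print.ndvi_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ndvi_grid> %d x %d @ %.4g m (%d/%d cells valid)%s\n",
              d[1], d[2], x$pixel_size, sum(!is.na(x$values)), prod(d),
              if (is.na(x$date)) "" else sprintf(", day %g", x$date)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Date-ordered stack of co-registered grids
#'
#' Bundles grids sharing one geometry (dimensions, pixel size, origin) into a
#' stack ordered by strictly increasing observation date.
#'
#' @param grids list of [ndvi_grid()] objects with dates set.
#' @return an object of class `grid_stack`.
#' @export
grid_stack <- function(grids) {
  if (!length(grids)) stop("empty grid list")
  if (!all(vapply(grids, inherits, logical(1), "ndvi_grid")))
    stop("all elements must be ndvi_grid objects")
  dates <- vapply(grids, function(g) g$date, numeric(1))
  if (anyNA(dates)) stop("all grids in a stack need a date")
  grids <- grids[order(dates)]
  dates <- sort(dates)
  if (any(diff(dates) <= 0)) stop("dates must be strictly increasing")
  g1 <- grids[[1]]
  for (g in grids[-1])
    if (!same_geometry(g1, g)) stop("grids do not share one geometry")
  structure(list(grids = grids, dates = dates), class = "grid_stack")
}

#' @export
length.grid_stack <- function(x) length(x$grids)

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d date(s): %s\n", length(x$grids),
              paste(x$dates, collapse = ", ")))
  print(x$grids[[1]])
  invisible(x)
}

stack_dates <- function(stack) stack$dates

# mask of pixels observed on every date
stack_complete_mask <- function(stack) {
  Reduce(`&`, lapply(stack$grids, valid_mask))
}
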