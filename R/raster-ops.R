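# Co-registration, temporal interpolation and seasonal summation of stacks.

# overlap lengths between two sets of 1-D intervals given as (lo, hi) matrices
interval_overlap <- function(lo_t, hi_t, lo_s, hi_s) {
  pmax(outer(hi_t, hi_s, pmin) - outer(lo_t, lo_s, pmax), 0)
}

#' Resample grids onto the geometry of the coarsest member
#'
#' Area-weighted resampling: every grid is averaged onto the cell lattice of
#' the member with the largest pixel size, restricted to cells of that lattice
#' lying fully inside the spatial intersection of all inputs. An output cell is
#' valid only where at least half of its area is covered by valid source
#' pixels; its value is the valid-area-weighted mean. Grids already sharing the
#' target geometry are passed through unchanged.
#'
#' @param grids list of [ndvi_grid()] objects (dated, co-projected,
#'   overlapping extents).
#' @param min_coverage minimum valid-area fraction for an output cell.
#' @return a [grid_stack()] on the common coarsest geometry.
#' @export
resample_to_coarsest <- function(grids, min_coverage = 0.5) {
  if (!length(grids)) stop("need at least one grid")
  ps <- vapply(grids, function(g) g$pixel_size, numeric(1))
  coarse <- grids[[which.max(ps)]]
  if (all(vapply(grids, same_geometry, logical(1), b = coarse)))
    return(grid_stack(grids))

  ext <- vapply(grids, grid_extent, numeric(4))
  xi <- c(max(ext["xmin", ]), min(ext["xmax", ]))
  yi <- c(max(ext["ymin", ]), min(ext["ymax", ]))
  tol <- coarse$pixel_size * 1e-9
  if (xi[2] - xi[1] <= tol || yi[2] - yi[1] <= tol)
    stop("grids have an empty spatial intersection")

  dt <- dim(coarse$values); pst <- coarse$pixel_size
  cx_lo <- coarse$origin[1] + (seq_len(dt[2]) - 1) * pst
  cy_hi <- coarse$origin[2] - (seq_len(dt[1]) - 1) * pst
  cols <- which(cx_lo >= xi[1] - tol & cx_lo + pst <= xi[2] + tol)
  rows <- which(cy_hi <= yi[2] + tol & cy_hi - pst >= yi[1] - tol)
  if (!length(cols) || !length(rows))
    stop("grids have an empty spatial intersection")
  t_origin <- c(cx_lo[cols[1]], cy_hi[rows[1]])
  lo_tx <- cx_lo[cols]; hi_tx <- lo_tx + pst
  hi_ty <- cy_hi[rows]; lo_ty <- hi_ty - pst
  cell_area <- pst^2

  out <- lapply(grids, function(g) {
    d <- dim(g$values); psg <- g$pixel_size
    lo_sx <- g$origin[1] + (seq_len(d[2]) - 1) * psg; hi_sx <- lo_sx + psg
    hi_sy <- g$origin[2] - (seq_len(d[1]) - 1) * psg; lo_sy <- hi_sy - psg
    Ox <- interval_overlap(lo_tx, hi_tx, lo_sx, hi_sx)  # tcols x scols
    Oy <- interval_overlap(lo_ty, hi_ty, lo_sy, hi_sy)  # trows x srows
    M <- valid_mask(g)
    V <- g$values; V[!M] <- 0
    covered <- Oy %*% M %*% t(Ox)
    sums <- Oy %*% V %*% t(Ox)
    vals <- sums / covered
    vals[covered < min_coverage * cell_area] <- NA_real_
    ndvi_grid(vals, pixel_size = pst, origin = t_origin, date = g$date,
              range = g$range, clamp_tol = 0.01)
  })
  grid_stack(out)
}

#' Interpolate a stack to one grid per day
#'
#' Linearly interpolates each pixel's trajectory through its observed values,
#' producing one grid per calendar day from the first to the last observation
#' date inclusive. A pixel missing on any observation date is treated as
#' missing on every interpolated day (complete-case trajectories).
#'
#' @param stack a [grid_stack()] with at least two dates.
#' @return a daily [grid_stack()].
#' @export
interpolate_daily <- function(stack) {
  stopifnot(inherits(stack, "grid_stack"))
  dates <- stack$dates
  if (length(dates) < 2) stop("daily interpolation needs at least two dates")
  keep <- stack_complete_mask(stack)
  days <- seq(dates[1], dates[length(dates)])
  g1 <- stack$grids[[1]]
  out <- lapply(days, function(day) {
    i <- findInterval(day, dates, rightmost.closed = TRUE)
    if (i == length(dates)) i <- i - 1L
    w <- (day - dates[i]) / (dates[i + 1] - dates[i])
    v <- (1 - w) * stack$grids[[i]]$values + w * stack$grids[[i + 1]]$values
    v[!keep] <- NA_real_
    ndvi_grid(v, pixel_size = g1$pixel_size, origin = g1$origin, date = day,
              range = g1$range)
  })
  grid_stack(out)
}

#' Per-pixel sum of a stack across dates
#'
#' Sums every pixel over all dates in the stack; a pixel is valid in the sum
#' only where it is valid on every date. Applied to an observation stack this
#' yields the seasonal NDVI sum; applied to a daily interpolated stack it
#' yields the daily-integrated seasonal sum. Output values may exceed 1 (units
#' NDVI x date), so the result carries no value range.
#'
#' @param stack a [grid_stack()].
#' @return an [ndvi_grid()] with `range = NULL` and no date.
#' @export
sum_stack <- function(stack) {
  stopifnot(inherits(stack, "grid_stack"))
  v <- Reduce(`+`, lapply(stack$grids, function(g) g$values))
  g1 <- stack$grids[[1]]
  ndvi_grid(v, pixel_size = g1$pixel_size, origin = g1$origin,
            date = NA_real_, range = NULL)
}
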