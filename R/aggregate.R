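# Block aggregation to coarser grains and variance/skewness scale profiles.

#' Block-average a grid by an integer factor
#'
#' Aggregates non-overlapping `factor` x `factor` pixel blocks, anchored at the
#' grid origin, into single output pixels. The output value is the mean of the
#' block's valid cells; the output cell is valid only if at least
#' `min_coverage` of the block's cells are valid. Trailing partial blocks at
#' the southern and eastern edges are dropped, so the output spans
#' `floor(dim / factor)` blocks and the origin is unchanged.
#'
#' @param grid an [ndvi_grid()].
#' @param factor positive integer aggregation factor (1 = identity).
#' @param min_coverage minimum valid fraction of a block.
#' @return an [ndvi_grid()] with `pixel_size * factor`.
#' @export
block_average <- function(grid, factor, min_coverage = 0.5) {
  stopifnot(inherits(grid, "ndvi_grid"))
  f <- as.integer(factor)
  if (f < 1) stop("factor must be a positive integer")
  d <- dim(grid$values)
  if (f > min(d)) stop("factor exceeds a grid dimension")
  if (f == 1L) return(grid)
  nr <- (d[1] %/% f) * f; nc <- (d[2] %/% f) * f
  v <- grid$values[seq_len(nr), seq_len(nc), drop = FALSE]
  m <- !is.na(v)
  v[!m] <- 0
  rg <- gl(nr / f, f); cg <- gl(nc / f, f)
  sums <- t(rowsum(t(rowsum(v, rg)), cg))
  counts <- t(rowsum(t(rowsum(m + 0, rg)), cg))
  out <- sums / counts
  out[counts < min_coverage * f^2] <- NA_real_
  ndvi_grid(out, pixel_size = grid$pixel_size * f, origin = grid$origin,
            date = grid$date, range = grid$range)
}

#' Aggregation factor nearest a target grain length
#'
#' @param grid an [ndvi_grid()].
#' @param target_length target grain in metres (at least one pixel).
#' @return integer factor `round(target_length / pixel_size)`, minimum 1.
#' @export
grain_for_length <- function(grid, target_length) {
  stopifnot(target_length >= grid$pixel_size)
  max(1L, as.integer(round(target_length / grid$pixel_size)))
}

#' Default ladder of aggregation factors
#'
#' Near-log-uniform integer factors (powers of sqrt(2), rounded), truncated so
#' each aggregated grid keeps a workable number of cells, optionally augmented
#' with the exact factors matching given target grain lengths (e.g. the 12 m
#' harvester footprint and the 30 m satellite pixel).
#'
#' @param grid an [ndvi_grid()].
#' @param target_lengths optional grain lengths in metres to include exactly.
#' @return sorted integer vector of factors starting at 1.
#' @export
scale_factor_ladder <- function(grid, target_lengths = NULL) {
  base <- c(1L, 2L, 3L, 4L, 6L, 8L, 11L, 16L, 23L, 32L, 45L, 64L, 91L, 128L,
            181L, 256L)
  f <- base
  if (!is.null(target_lengths))
    f <- c(f, vapply(target_lengths, grain_for_length, integer(1), grid = grid))
  d <- dim(grid$values)
  f <- f[f <= min(d) & (d[1] %/% f) * (d[2] %/% f) >= 10L]  # profile-fittable
  sort(unique(f))
}

# population variance and adjusted Fisher-Pearson skewness
pop_variance <- function(x) mean((x - mean(x))^2)

sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m2 <- pop_variance(x)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Variance, variance-loss and skewness profile across spatial grains
#'
#' Block-averages the grid at each factor and reports, over the valid cells of
#' each aggregated grid: the population variance, the fraction of native-grain
#' variance lost, the adjusted Fisher-Pearson skewness, and a maximum
#' likelihood Beta fit of the aggregated values. Degenerate cases (constant
#' aggregated grid) report zero skewness and `NA` Beta parameters and are
#' flagged in the `degenerate` column.
#'
#' @param grid an [ndvi_grid()] with values in (0, 1).
#' @param factors ascending integer factors starting at 1; default
#'   [scale_factor_ladder()].
#' @return a data frame of class `scale_profile` with columns `factor`,
#'   `grain_length`, `n_cells`, `variance`, `variance_loss_fraction`,
#'   `skewness`, `alpha`, `beta`, `degenerate`.
#' @export
scale_profile <- function(grid, factors = scale_factor_ladder(grid)) {
  stopifnot(inherits(grid, "ndvi_grid"))
  factors <- as.integer(factors)
  if (factors[1] != 1L || is.unsorted(factors, strictly = TRUE))
    stop("factors must be ascending and start at 1")
  rows <- lapply(factors, function(f) {
    ba <- block_average(grid, f)
    x <- grid_values(ba)
    if (length(x) < 10)
      stop(sprintf("factor %d leaves %d valid cells (< 10)", f, length(x)))
    v <- pop_variance(x)
    sk <- sample_skewness(x)
    degen <- v == 0 || is.na(sk)
    if (degen) sk <- 0
    fit <- if (v == 0) c(alpha = NA_real_, beta = NA_real_) else
      tryCatch(fit_beta_mle(x),
               error = function(e) c(alpha = NA_real_, beta = NA_real_))
    data.frame(factor = f, grain_length = f * grid$pixel_size,
               n_cells = length(x), variance = v,
               skewness = sk, alpha = fit[["alpha"]], beta = fit[["beta"]],
               degenerate = degen)
  })
  out <- do.call(rbind, rows)
  v0 <- out$variance[1]
  loss <- if (v0 > 0) 1 - out$variance / v0 else rep(0, nrow(out))
  loss[loss < 0 & loss > -1e-12] <- 0
  out$variance_loss_fraction <- loss
  out <- out[, c("factor", "grain_length", "n_cells", "variance",
                 "variance_loss_fraction", "skewness", "alpha", "beta",
                 "degenerate")]
  if (any(out$degenerate))
    message(sum(out$degenerate), " degenerate grain(s): skewness reported as 0")
  class(out) <- c("scale_profile", "data.frame")
  out
}
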