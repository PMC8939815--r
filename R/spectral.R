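# Radially-averaged power spectral density and power-law scale analysis.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Radially-averaged power spectral density of a grid
#'
#' Subtracts the valid-cell mean (invalid cells are filled with that mean
#' first, so the field boundary injects no spurious edge), optionally applies
#' a separable 2-D Hann taper, computes the 2-D discrete Fourier transform,
#' and averages the normalized power `|F|^2 / N^2` (`N` = total cell count) in
#' annular wavenumber bins. Untapered, the total power over all non-DC
#' frequencies equals the population variance of the mean-removed image
#' (Parseval's identity pins the normalization).
#'
#' Bins are integer multiples of `delta_k = 1 / (L * pixel_size)` (`L` = the
#' larger grid dimension); each frequency-lattice cell joins the bin nearest
#' its radius `|k|`, and the reported bin center is the mean radius of its
#' members, which avoids empty low-frequency bins. `k` is in cycles per metre
#' (no 2 pi factor), so a wavelength of `w` metres sits at `k = 1/w`.
#'
#' @param grid an [ndvi_grid()] of at least 32 x 32 cells with at least half
#'   of them valid.
#' @param taper apply a 2-D Hann taper (default `TRUE`). Use `FALSE` when the
#'   Parseval normalization matters.
#' @return a data frame of class `radial_spectrum` with columns `k`, `power`,
#'   `n` (lattice cells per bin) and attributes `pixel_size`, `dim`, `taper`,
#'   `delta_k`.
#' @export
radial_psd <- function(grid, taper = TRUE) {
  stopifnot(inherits(grid, "ndvi_grid"))
  d <- dim(grid$values)
  if (min(d) < 32) stop("grid must be at least 32 x 32")
  m <- valid_mask(grid)
  if (mean(m) < 0.5) stop("more than 50% invalid cells; mean fill would dominate")
  v <- grid$values
  mu <- mean(v[m])
  v[!m] <- mu
  v <- v - mean(v)
  if (taper) v <- v * outer(hann_window(d[1]), hann_window(d[2]))
  N <- prod(d)
  P <- Mod(stats::fft(v))^2 / N^2
  kmat <- wavenumber_grid(d[1], d[2], grid$pixel_size)
  dk <- 1 / (max(d) * grid$pixel_size)
  bin <- round(kmat / dk)
  keep <- bin > 0
  b <- bin[keep]
  out <- data.frame(
    k = as.numeric(tapply(kmat[keep], b, mean)),
    power = as.numeric(tapply(P[keep], b, mean)),
    n = as.integer(tapply(P[keep], b, length))
  )
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  attr(out, "pixel_size") <- grid$pixel_size
  attr(out, "grid_dim") <- d
  attr(out, "taper") <- taper
  attr(out, "delta_k") <- dk
  class(out) <- c("radial_spectrum", "data.frame")
  out
}

#' Fit a power law to a radial spectrum
#'
#' Ordinary least squares of `ln(power)` on `ln(k)` over the bins inside
#' `k_range`, i.e. the model `power = c * k^b`. The exponent `b` is reported
#' as the signed log-log slope: negative for red spectra with variance
#' concentrated at large spatial scales. Zero-power bins inside the range are
#' dropped (with a message).
#'
#' @param spectrum a [radial_psd()] result.
#' @param k_range `c(k_min, k_max)` in cycles per metre; at least 5 usable
#'   bins must fall inside.
#' @return list of class `power_law_fit` with `b`, `c`, `k_range`,
#'   `r_squared`, `n_bins`.
#' @export
fit_power_law <- function(spectrum, k_range = c(0, Inf)) {
  stopifnot(inherits(spectrum, "data.frame"), length(k_range) == 2)
  inr <- spectrum$k >= k_range[1] & spectrum$k <= k_range[2]
  zero <- inr & spectrum$power <= 0
  if (any(zero)) message(sum(zero), " zero-power bin(s) dropped from fit")
  s <- spectrum[inr & spectrum$power > 0, ]
  if (nrow(s) < 5) stop("fewer than 5 usable bins inside k_range")
  fit <- stats::lm(log(power) ~ log(k), data = s)
  structure(list(b = unname(stats::coef(fit)[2]),
                 c = unname(exp(stats::coef(fit)[1])),
                 k_range = k_range,
                 r_squared = summary(fit)$r.squared,
                 n_bins = nrow(s)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> power = %.4g * k^%.4g over k in [%g, %g] (R2 = %.3f, %d bins)\n",
              x$c, x$b, x$k_range[1], x$k_range[2], x$r_squared, x$n_bins))
  invisible(x)
}

#' Detect a candidate spectral scale break
#'
#' Greedy search over bin boundaries for the split that most improves a
#' two-segment log-log fit over the single-segment fit, with at least
#' `min_bins` bins per segment. Each bin is weighted by its annulus member
#' count (the variance of a mean log power shrinks with the number of
#' contributing frequency cells, and the few-member low-k bins would otherwise
#' dominate the split). A break is flagged when the weighted squared error
#' improves by at least `threshold` (fraction of the one-segment error); the
#' break frequency is the geometric mean of the bins flanking the best split.
#'
#' @param spectrum a [radial_psd()] result.
#' @param min_bins minimum bins per segment.
#' @param threshold fractional error-improvement needed to flag a break.
#' @return list with `has_break`, `k_break` (`NA` when none), `improvement`,
#'   `b_below`, `b_above`.
#' @export
find_scale_break <- function(spectrum, min_bins = 5, threshold = 0.05) {
  s <- spectrum[spectrum$power > 0, ]
  n <- nrow(s)
  if (n < 2 * min_bins) stop("too few bins for a two-segment fit")
  lx <- log(s$k); ly <- log(s$power); sw <- sqrt(s$n)
  wfit <- function(i, j) {
    f <- stats::.lm.fit(cbind(sw[i:j], sw[i:j] * lx[i:j]), sw[i:j] * ly[i:j])
    list(sse = sum(f$residuals^2), b = f$coefficients[2])
  }
  one <- wfit(1, n)
  best <- Inf; bi <- NA_integer_
  for (i in min_bins:(n - min_bins)) {
    v <- wfit(1, i)$sse + wfit(i + 1, n)$sse
    if (v < best) { best <- v; bi <- i }
  }
  improvement <- 1 - best / one$sse
  has_break <- is.finite(improvement) && improvement >= threshold
  list(has_break = has_break,
       k_break = if (has_break) sqrt(s$k[bi] * s$k[bi + 1]) else NA_real_,
       improvement = improvement,
       b_below = wfit(1, bi)$b, b_above = wfit(bi + 1, n)$b)
}

#' Power-law fits per date and wavenumber range, with break detection
#'
#' Computes the radial power spectrum of every grid in the stack and fits
#' `power = c * k^b` over each requested range; additionally runs
#' [find_scale_break()] on each date's full spectrum. The default ranges fit
#' the low-frequency regime below 2 cycles per metre and the high-frequency
#' regime above 10 cycles per metre.
#'
#' @param stack a [grid_stack()] on one geometry.
#' @param ranges list of `c(k_min, k_max)` ranges.
#' @param taper passed to [radial_psd()].
#' @param break_threshold passed to [find_scale_break()].
#' @return data frame with one row per (date, range): `date`, `k_min`,
#'   `k_max`, `b`, `c`, `r_squared`, `n_bins`; the per-date break table is in
#'   `attr(, "breaks")`.
#' @export
spectral_report <- function(stack, ranges = list(c(0, 2), c(10, Inf)),
                            taper = TRUE, break_threshold = 0.05) {
  stopifnot(inherits(stack, "grid_stack"))
  fits <- list(); breaks <- list()
  for (i in seq_along(stack$grids)) {
    sp <- radial_psd(stack$grids[[i]], taper = taper)
    for (r in ranges) {
      f <- fit_power_law(sp, r)
      fits[[length(fits) + 1L]] <- data.frame(
        date = stack$dates[i], k_min = r[1], k_max = r[2],
        b = f$b, c = f$c, r_squared = f$r_squared, n_bins = f$n_bins)
    }
    br <- find_scale_break(sp, threshold = break_threshold)
    breaks[[i]] <- data.frame(date = stack$dates[i], has_break = br$has_break,
                              k_break = br$k_break,
                              improvement = br$improvement,
                              b_below = br$b_below, b_above = br$b_above)
  }
  out <- do.call(rbind, fits)
  attr(out, "breaks") <- do.call(rbind, breaks)
  out
}
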