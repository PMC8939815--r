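# Synthetic multi-date NDVI fields with known Beta marginals and power-law
# spectra, plus serpentine harvester transects driven by those fields.

fft_freqs <- function(n, pixel_size) {
  half <- n %/% 2
  c(0:half, -((n - half - 1):1))[seq_len(n)] / (n * pixel_size)
}

# |k| lattice in cycles per metre for an nr x nc grid
wavenumber_grid <- function(nr, nc, pixel_size) {
  fy <- fft_freqs(nr, pixel_size)
  fx <- fft_freqs(nc, pixel_size)
  sqrt(outer(fy^2, fx^2, `+`))
}

# spectral amplitude profile ~ k^(-b/2), optionally steepening to b_above
# beyond k_break (continuous at the break); DC forced to zero
power_law_amplitude <- function(kmat, b, k_break = NULL, b_above = NULL) {
  A <- ifelse(kmat > 0, kmat^(-b / 2), 0)
  if (!is.null(k_break)) {
    stopifnot(!is.null(b_above), k_break > 0)
    scale_hi <- k_break^((b_above - b) / 2)
    hi <- kmat >= k_break
    A[hi] <- scale_hi * kmat[hi]^(-b_above / 2)
  }
  A
}

# Gaussian random field with power spectrum ~ amplitude^2: FFT-filter white
# noise (spectral phases exactly uniform), zero-mean by construction (zero DC)
filter_white_noise <- function(noise, amplitude) {
  n <- length(noise)
  Re(stats::fft(amplitude * stats::fft(noise), inverse = TRUE)) / n
}

# rank-based probability integral transform onto a Beta(alpha, beta) marginal:
# the output is exactly the Beta quantile set of size n, spatially arranged by
# the ranks of the latent field
rank_to_beta <- function(field, alpha, beta) {
  n <- length(field)
  u <- (rank(field, ties.method = "average") - 0.5) / n
  matrix(stats::qbeta(u, alpha, beta), nrow(field), ncol(field))
}

#' Match Beta shape parameters to a mean and standard deviation
#'
#' @param mean,sd target moments; `mean` in (0, 1) and `sd` small enough that
#'   `sd^2 < mean (1 - mean)`.
#' @return named numeric `c(alpha, beta)`.
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0, sd^2 < mean * (1 - mean))
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Synthesize one grid with a power-law spectrum and Beta marginal
#'
#' Generates a Gaussian random field by spectrally filtering white noise with
#' amplitude proportional to \eqn{k^{-b/2}} (zero DC component; the mean enters
#' through the marginal), then maps it onto the requested Beta marginal by a
#' rank-based probability integral transform. The transform is monotone, so the
#' spatial pattern is preserved exactly while the marginal becomes the exact
#' Beta quantile set; the monotone distortion of the spectrum is small (the
#' fitted exponent stays within about 0.15 of `-b`).
#'
#' A two-segment spectrum is available through `k_break`/`b_above`: amplitude
#' follows exponent `b` below the break frequency and `b_above` beyond it,
#' continuous at the break.
#'
#' @param shape `c(rows, cols)` of the output grid.
#' @param pixel_size pixel side length in metres.
#' @param b power-law exponent of the target power spectrum (power ~ `k^-b`).
#' @param marginal `c(alpha, beta)` of the target Beta marginal.
#' @param seed integer seed; identical arguments give bit-identical grids.
#' @param k_break optional break frequency in cycles per metre.
#' @param b_above exponent beyond `k_break` (required with `k_break`).
#' @param date optional ordinal day for the grid.
#' @return a fully-valid [ndvi_grid()].
#' @export
synthesize_grid <- function(shape, pixel_size, b, marginal, seed,
                            k_break = NULL, b_above = NULL, date = NA_real_) {
  stopifnot(length(shape) == 2, all(shape >= 16), is.finite(b), b >= 0,
            all(is.finite(marginal)), all(marginal > 0), pixel_size > 0)
  set.seed(seed)
  W <- matrix(stats::rnorm(shape[1] * shape[2]), shape[1], shape[2])
  A <- power_law_amplitude(wavenumber_grid(shape[1], shape[2], pixel_size),
                           b, k_break, b_above)
  field <- filter_white_noise(W, A)
  ndvi_grid(rank_to_beta(field, marginal[1], marginal[2]),
            pixel_size = pixel_size, origin = c(0, shape[1] * pixel_size),
            date = date)
}

#' Specification of a synthetic multi-date field
#'
#' @param shape `c(rows, cols)`, both at least 16.
#' @param pixel_size pixel side length in metres.
#' @param dates strictly increasing ordinal days, one per acquisition.
#' @param marginals list of `c(alpha, beta)` Beta parameters, one per date.
#' @param spectral_exponent power-law exponent `b` per date (recycled if
#'   length 1); power spectrum ~ `k^-b`.
#' @param coherence fraction in `[0, 1]` of spatial pattern variance shared
#'   across dates (1 = identical ranks on every date, 0 = independent dates).
#' @param seed integer seed.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(shape, pixel_size, dates, marginals, spectral_exponent,
                       coherence = 0.8, seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 16), pixel_size > 0,
            length(dates) >= 1, !is.unsorted(dates, strictly = TRUE),
            length(marginals) == length(dates),
            all(vapply(marginals, function(m) all(m > 0), logical(1))),
            all(spectral_exponent >= 0),
            coherence >= 0, coherence <= 1)
  b <- rep_len(spectral_exponent, length(dates))
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 dates = dates, marginals = marginals, spectral_exponent = b,
                 coherence = coherence, seed = as.integer(seed)),
            class = "field_spec")
}

#' Emulation preset for a four-date winter wheat season
#'
#' Four acquisitions (ordinal days 140, 160, 183, 202 of a leap year: May 19,
#' June 8, July 1, July 20) with Beta marginals moment-matched to per-date
#' means 0.91, 0.88, 0.44, 0.27 and standard deviations 0.014, 0.025, 0.063,
#' 0.011 — a green-up-then-senescence trajectory whose early dates are strongly
#' negatively skewed simply because their means sit near the upper bound — and
#' per-date spectral exponents 2.0, 2.3, 2.4, 3.2. A realistic default, not a
#' dataset to be reproduced.
#'
#' @param shape,pixel_size,seed,coherence overrides of the preset geometry.
#' @return a [field_spec()].
#' @export
wheat_season_spec <- function(shape = c(512, 512), pixel_size = 0.1343,
                               seed = 1, coherence = 0.8) {
  means <- c(0.91, 0.88, 0.44, 0.27)
  sds <- c(0.014, 0.025, 0.063, 0.011)
  field_spec(shape, pixel_size, dates = c(140, 160, 183, 202),
             marginals = Map(beta_from_moments, means, sds),
             spectral_exponent = c(2.0, 2.3, 2.4, 3.2),
             coherence = coherence, seed = seed)
}

#' Synthesize a coherent multi-date season
#'
#' One latent white-noise field is shared by all dates and mixed with per-date
#' independent noise using weight `coherence` (on the variance scale), then
#' spectrally filtered with each date's exponent and mapped onto each date's
#' Beta marginal. With `coherence = 1` and equal exponents all dates are
#' rank-identical; with `coherence = 0` dates are independent. Deterministic
#' given the spec's seed.
#'
#' @param spec a [field_spec()].
#' @return a fully-valid [grid_stack()].
#' @export
synthesize_season <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  FL <- stats::fft(matrix(stats::rnorm(nr * nc), nr, nc))
  kmat <- wavenumber_grid(nr, nc, spec$pixel_size)
  wl <- sqrt(spec$coherence); wd <- sqrt(1 - spec$coherence)
  grids <- lapply(seq_along(spec$dates), function(i) {
    FD <- stats::fft(matrix(stats::rnorm(nr * nc), nr, nc))
    A <- power_law_amplitude(kmat, spec$spectral_exponent[i])
    field <- Re(stats::fft(A * (wl * FL + wd * FD), inverse = TRUE)) / (nr * nc)
    m <- spec$marginals[[i]]
    ndvi_grid(rank_to_beta(field, m[1], m[2]), pixel_size = spec$pixel_size,
              origin = c(0, nr * spec$pixel_size), date = spec$dates[i])
  })
  grid_stack(grids)
}

#' Specification of a synthetic harvester run
#'
#' @param yield_coefficients numeric vector, intercept followed by one
#'   coefficient per stack date (yield units per unit NDVI).
#' @param gpc_coefficients intercept followed by one coefficient per date
#'   (percent protein per unit NDVI).
#' @param swath_width cross-track header width in metres (track spacing).
#' @param point_spacing along-track distance between records in metres.
#' @param noise_sd_yield,noise_sd_gpc Gaussian noise standard deviations.
#' @param target_r2_yield,target_r2_gpc optional true-model R-squared targets
#'   in (0, 1); when set, the corresponding noise standard deviation is
#'   derived from the realized signal variance
#'   (`sd(signal) * sqrt((1 - R2) / R2)`) instead of the fixed `noise_sd_*`.
#' @param seed integer seed.
#' @return an object of class `harvest_spec`.
#' @export
harvest_spec <- function(yield_coefficients, gpc_coefficients,
                         swath_width = 12, point_spacing = 1,
                         noise_sd_yield = 0, noise_sd_gpc = 0,
                         target_r2_yield = NULL, target_r2_gpc = NULL,
                         seed = 1) {
  stopifnot(swath_width > 0, point_spacing > 0,
            noise_sd_yield >= 0, noise_sd_gpc >= 0,
            length(yield_coefficients) >= 1, length(gpc_coefficients) >= 1,
            is.null(target_r2_yield) ||
              (target_r2_yield > 0 && target_r2_yield < 1),
            is.null(target_r2_gpc) || (target_r2_gpc > 0 && target_r2_gpc < 1))
  structure(list(yield_coefficients = yield_coefficients,
                 gpc_coefficients = gpc_coefficients,
                 swath_width = swath_width, point_spacing = point_spacing,
                 noise_sd_yield = noise_sd_yield, noise_sd_gpc = noise_sd_gpc,
                 target_r2_yield = target_r2_yield,
                 target_r2_gpc = target_r2_gpc,
                 seed = as.integer(seed)),
            class = "harvest_spec")
}

# serpentine north-south transects: one pass per swath, alternating direction
serpentine_points <- function(extent, swath_width, point_spacing) {
  xs <- seq(extent["xmin"] + swath_width / 2, by = swath_width,
            length.out = max(0, floor((extent["xmax"] - extent["xmin"]) / swath_width)))
  if (!length(xs)) stop("field too narrow to contain one full harvester track")
  ys <- seq(extent["ymin"] + point_spacing / 2, extent["ymax"] - point_spacing / 2,
            by = point_spacing)
  if (!length(ys)) stop("field too short to contain one full harvester track")
  pts <- do.call(rbind, lapply(seq_along(xs), function(j) {
    yy <- if (j %% 2 == 1) ys else rev(ys)       # northbound, then southbound
    data.frame(x = xs[j], y = yy, pass = j,
               heading = if (j %% 2 == 1) 0 else 180)
  }))
  rownames(pts) <- NULL
  pts
}

#' Simulate a harvester table over a synthetic season
#'
#' Lays serpentine north-south passes spaced one swath width apart across the
#' stack's extent, with one record every `point_spacing` metres, then draws
#' yield and grain protein content (GPC) for each record as linear functions of
#' the per-date footprint-mean NDVI plus Gaussian noise. Footprint means are
#' computed with [extract_buffer_means()], so the generator and the analysis
#' share one footprint definition.
#'
#' @param stack a [grid_stack()] covering the field.
#' @param spec a [harvest_spec()] whose coefficient vectors have one intercept
#'   plus one entry per stack date.
#' @return a data frame with columns `x`, `y`, `pass`, `heading`, one
#'   `ndvi_<day>` column per date, `sum_ndvi`, `yield` and `gpc`.
#' @export
synthesize_harvest <- function(stack, spec) {
  stopifnot(inherits(stack, "grid_stack"), inherits(spec, "harvest_spec"))
  nd <- length(stack)
  if (length(spec$yield_coefficients) != nd + 1 ||
      length(spec$gpc_coefficients) != nd + 1)
    stop("coefficient vectors must be intercept plus one entry per date")
  ext <- grid_extent(stack$grids[[1]])
  pts <- serpentine_points(ext, spec$swath_width, spec$point_spacing)
  tab <- extract_buffer_means(stack, pts, width = spec$swath_width,
                              along = spec$point_spacing)
  ndvi_cols <- paste0("ndvi_", stack$dates)
  X <- as.matrix(tab[, ndvi_cols, drop = FALSE])
  tab$sum_ndvi <- rowSums(X)
  set.seed(spec$seed)
  n <- nrow(tab)
  sig_y <- spec$yield_coefficients[1] + drop(X %*% spec$yield_coefficients[-1])
  sig_g <- spec$gpc_coefficients[1] + drop(X %*% spec$gpc_coefficients[-1])
  sd_for_r2 <- function(signal, r2) stats::sd(signal) * sqrt((1 - r2) / r2)
  sd_y <- if (is.null(spec$target_r2_yield)) spec$noise_sd_yield
          else sd_for_r2(sig_y, spec$target_r2_yield)
  sd_g <- if (is.null(spec$target_r2_gpc)) spec$noise_sd_gpc
          else sd_for_r2(sig_g, spec$target_r2_gpc)
  tab$yield <- sig_y + stats::rnorm(n, 0, sd_y)
  tab$gpc <- sig_g + stats::rnorm(n, 0, sd_g)
  tab
}
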