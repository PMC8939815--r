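# Harvester footprint buffers, footprint-mean extraction, and exhaustive
# AIC model selection linking NDVI to yield and grain protein.

#' Rectangular harvester footprint around a record
#'
#' Builds the footprint polygon of one harvester record: a rectangle centered
#' on the point, `width` metres across the track (the cut width of the
#' header, perpendicular to travel) and `along` metres along the travel
#' direction (the per-record advance).
#'
#' @param x,y point coordinates in metres.
#' @param heading travel heading in degrees clockwise from north.
#' @param width cross-track footprint width in metres (default 12).
#' @param along along-track footprint length in metres (default 1).
#' @return a closed 5 x 2 matrix of corner coordinates with attribute `area`.
#' @export
make_buffer <- function(x, y, heading, width = 12, along = 1) {
  stopifnot(is.finite(heading))
  th <- heading * pi / 180
  u <- c(sin(th), cos(th))    # along travel
  v <- c(cos(th), -sin(th))   # across travel
  h <- along / 2; w <- width / 2
  corners <- rbind(
    c(x, y) + h * u + w * v,
    c(x, y) + h * u - w * v,
    c(x, y) - h * u - w * v,
    c(x, y) - h * u + w * v
  )
  ring <- rbind(corners, corners[1, ])
  colnames(ring) <- c("x", "y")
  attr(ring, "area") <- width * along
  ring
}

#' Estimate travel headings from consecutive points
#'
#' Headings (degrees clockwise from north) from each point to its successor on
#' the same pass; the last point of a pass inherits its predecessor's heading.
#' Passes are taken from a `pass` column when present, otherwise a new pass
#' starts wherever the step exceeds `break_factor` times the median step.
#'
#' @param points data frame with `x`, `y` and optionally `pass`.
#' @param break_factor step-length multiple that starts a new pass.
#' @return numeric vector of headings.
#' @export
estimate_headings <- function(points, break_factor = 2.5) {
  n <- nrow(points)
  if (n < 2) stop("need at least two points to estimate headings")
  dx <- diff(points$x); dy <- diff(points$y)
  if (!is.null(points$pass)) {
    newpass <- diff(as.integer(factor(points$pass))) != 0
  } else {
    step <- sqrt(dx^2 + dy^2)
    newpass <- step > break_factor * stats::median(step)
  }
  hd <- (atan2(dx, dy) * 180 / pi) %% 360
  out <- rep(NA_real_, n)
  out[seq_len(n - 1)][!newpass] <- hd[!newpass]
  for (i in 2:n) if (is.na(out[i])) out[i] <- out[i - 1]
  if (is.na(out[1])) out[1] <- out[2]
  if (anyNA(out)) stop("could not estimate headings (isolated points)")
  out
}

#' Footprint-mean raster values at harvester points
#'
#' For every point and every grid, averages the values of the pixels whose
#' centers fall inside the point's rectangular footprint ([make_buffer()]).
#' Rows whose footprint captures fewer than `min_coverage` of the expected
#' pixel count (footprint area / pixel area) in any grid are dropped, with a
#' message; the dropped row indices are in `attr(, "dropped")`.
#'
#' @param grids a [grid_stack()] (columns named `ndvi_<day>`) or a named list
#'   of [ndvi_grid()] objects (columns take the list names).
#' @param points data frame with `x`, `y` and optionally `heading` (estimated
#'   with [estimate_headings()] when absent) and `pass`.
#' @param width,along footprint dimensions in metres.
#' @param min_coverage minimum captured fraction of the expected pixel count.
#' @return `points` with one footprint-mean column per grid.
#' @export
extract_buffer_means <- function(grids, points, width = 12, along = 1,
                                 min_coverage = 0.5) {
  if (inherits(grids, "grid_stack")) {
    glist <- grids$grids
    names(glist) <- paste0("ndvi_", grids$dates)
  } else {
    glist <- grids
    if (is.null(names(glist)) || any(!nzchar(names(glist))))
      stop("grid list must be named")
  }
  stopifnot(all(c("x", "y") %in% names(points)))
  n <- nrow(points)
  heading <- if (!is.null(points$heading)) points$heading
             else estimate_headings(points)
  half_diag <- sqrt((width / 2)^2 + (along / 2)^2)
  th <- heading * pi / 180
  ux <- sin(th); uy <- cos(th); vx <- cos(th); vy <- -sin(th)
  eps <- 1e-9
  means <- matrix(NA_real_, n, length(glist))
  counts <- matrix(0L, n, length(glist))
  for (j in seq_along(glist)) {
    g <- glist[[j]]
    ctr <- pixel_centers(g)
    for (i in seq_len(n)) {
      ci <- which(abs(ctr$x - points$x[i]) <= half_diag)
      ri <- which(abs(ctr$y - points$y[i]) <= half_diag)
      if (!length(ci) || !length(ri)) next
      X <- outer(rep(1, length(ri)), ctr$x[ci]) - points$x[i]
      Y <- outer(ctr$y[ri], rep(1, length(ci))) - points$y[i]
      s <- X * ux[i] + Y * uy[i]
      t <- X * vx[i] + Y * vy[i]
      inside <- abs(s) <= along / 2 + eps & abs(t) <= width / 2 + eps
      vals <- g$values[ri, ci, drop = FALSE][inside]
      vals <- vals[!is.na(vals)]
      counts[i, j] <- length(vals)
      if (length(vals)) means[i, j] <- mean(vals)
    }
  }
  expected <- width * along / vapply(glist, function(g) g$pixel_size^2, numeric(1))
  ok <- rowSums(sweep(counts, 2, min_coverage * expected, `<`)) == 0
  if (any(!ok))
    message(sum(!ok), " point(s) dropped: footprint coverage below ",
            min_coverage * 100, "% of the expected pixel count")
  out <- points
  out$heading <- heading
  for (j in seq_along(glist)) out[[names(glist)[j]]] <- means[, j]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- which(!ok)
  out
}

#' Exhaustive linear model selection by AIC
#'
#' Fits an ordinary least squares model for every admissible subset of the
#' named predictors (including the intercept-only model) and ranks them by
#' `AIC = n ln(RSS/n) + 2 (p + 2)` (Gaussian likelihood; the error variance
#' counts as a parameter). Akaike weights
#' `w_i = exp(-dAIC_i/2) / sum_j exp(-dAIC_j/2)` sum to one across all fitted
#' candidates.
#'
#' `exclusive` removes collinear-by-construction combinations: a named list
#' where each name is a predictor that may never co-occur with any predictor
#' in its entry (e.g. a seasonal NDVI sum alongside its own per-date addends).
#' Rank-deficient subsets are skipped with a message.
#'
#' @param response numeric response vector.
#' @param predictors named numeric matrix or data frame of candidate
#'   predictors.
#' @param exclusive named list of incompatible predictor sets.
#' @return list of class `model_selection`: `models` (data frame sorted by
#'   AIC with columns `model`, `k`, `aic`, `delta_aic`, `weight`,
#'   `r_squared`), `coefficients` (named list per model), `n`.
#' @export
all_subsets_lm <- function(response, predictors, exclusive = list()) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X)) || any(!nzchar(colnames(X))))
    stop("predictors must be named")
  y <- as.numeric(response)
  n <- length(y); p <- ncol(X)
  if (n != nrow(X)) stop("response and predictors disagree in length")
  if (n <= p + 2) stop("need n > p + 2 observations for the fullest model")
  if (p > 16) stop("more than 16 candidate predictors; not enumerable")
  nm <- colnames(X)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("degenerate response: zero variance")
  # floor RSS at a relative machine level so exact fits rank by the parameter
  # penalty instead of rounding noise in log(RSS)
  rss_floor <- tss * 1e-24
  subsets <- unlist(lapply(0:p, function(m) utils::combn(p, m, simplify = FALSE)),
                    recursive = FALSE)
  admissible <- function(cn) {
    for (k in names(exclusive))
      if (k %in% cn && any(exclusive[[k]] %in% cn)) return(FALSE)
    TRUE
  }
  rows <- list(); coefs <- list(); skipped <- 0L
  for (idx in subsets) {
    cn <- nm[idx]
    if (!admissible(cn)) next
    Xm <- cbind(`(Intercept)` = 1, X[, idx, drop = FALSE])
    f <- stats::.lm.fit(Xm, y)
    if (f$rank < ncol(Xm)) { skipped <- skipped + 1L; next }
    rss <- max(sum(f$residuals^2), rss_floor)
    label <- if (length(cn)) paste(cn, collapse = " + ") else "(intercept only)"
    rows[[length(rows) + 1L]] <- data.frame(
      model = label, k = length(cn),
      aic = n * log(rss / n) + 2 * (length(cn) + 2),
      r_squared = max(0, 1 - rss / tss))
    cf <- f$coefficients
    names(cf) <- colnames(Xm)
    coefs[[label]] <- cf
  }
  if (skipped) message(skipped, " rank-deficient subset(s) skipped")
  models <- do.call(rbind, rows)
  models$delta_aic <- models$aic - min(models$aic)
  w <- exp(-models$delta_aic / 2)
  models$weight <- w / sum(w)
  ord <- order(models$aic)
  models <- models[ord, c("model", "k", "aic", "delta_aic", "weight",
                          "r_squared")]
  rownames(models) <- NULL
  structure(list(models = models, coefficients = coefs[models$model], n = n),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %d candidate model(s), n = %d\n",
              nrow(x$models), x$n))
  print(utils::head(x$models, 10), digits = 4)
  invisible(x)
}

#' Single-predictor regressions of a response on each candidate
#'
#' Simple ordinary least squares of the response on each predictor separately,
#' with the two-sided t-test p-value of the slope.
#'
#' @param table data frame holding the response and predictors.
#' @param response name of the response column.
#' @param predictors names of predictor columns.
#' @return data frame with `predictor`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
per_date_regressions <- function(table, response, predictors) {
  y <- table[[response]]
  if (length(y) < 10) stop("need at least 10 rows")
  rows <- lapply(predictors, function(pn) {
    x <- table[[pn]]
    if (is.null(x)) stop("no such predictor column: ", pn)
    if (stats::sd(x) == 0) stop("degenerate predictor: ", pn)
    f <- stats::lm(y ~ x)
    sm <- summary(f)
    data.frame(predictor = pn, slope = unname(stats::coef(f)[2]),
               intercept = unname(stats::coef(f)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4], n = length(y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
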