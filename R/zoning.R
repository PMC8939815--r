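# Multi-temporal unsupervised zoning of NDVI stacks.

# k-means++ seeding: D^2-weighted center sampling (deterministic under the
# caller's RNG state)
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      centers[j, ] <- X[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Multi-date k-means classification of a stack
#'
#' Clusters the per-pixel multi-date NDVI vectors of the stack with k-means.
#' Only pixels valid on every date participate (complete case). Seeding is
#' k-means++ from the given seed, with `restarts` independent starts; the
#' solution with the lowest within-cluster sum of squares is kept, so results
#' are deterministic for a given seed.
#'
#' @param stack a [grid_stack()].
#' @param k number of fine classes (at least 2).
#' @param seed integer seed.
#' @param restarts independent k-means++ starts.
#' @return object of class `zone_map`: `labels` (integer matrix, 0 where any
#'   date is missing), `k`, `centers`, `tot_withinss`, `grouped = FALSE`.
#' @export
kmeans_stack <- function(stack, k = 50, seed = 1, restarts = 10) {
  stopifnot(inherits(stack, "grid_stack"), k >= 2)
  keep <- stack_complete_mask(stack)
  X <- vapply(stack$grids, function(g) g$values[keep], numeric(sum(keep)))
  if (!is.matrix(X)) X <- matrix(X, ncol = length(stack))
  if (nrow(X) < k) stop("fewer complete-case pixels than classes")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    ctr <- kmeanspp_centers(X, k)
    ctr <- ctr[!duplicated(ctr), , drop = FALSE]
    km <- suppressWarnings(tryCatch(
      stats::kmeans(X, centers = ctr, iter.max = 100),
      error = function(e) stats::kmeans(X, centers = ctr, iter.max = 100,
                                        algorithm = "Lloyd")
    ))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- matrix(0L, nrow(keep), ncol(keep))
  labels[keep] <- best$cluster
  structure(list(labels = labels, k = nrow(best$centers),
                 centers = best$centers, tot_withinss = best$tot.withinss,
                 grouped = FALSE, legend = NULL),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d class(es)%s over %d labeled pixel(s)\n", x$k,
              if (x$grouped) " (grouped)" else "", sum(x$labels > 0)))
  invisible(x)
}

#' Per-class per-date mean NDVI trajectories
#'
#' @param zones a [kmeans_stack()] or [group_classes()] result.
#' @param stack the co-registered [grid_stack()].
#' @return data frame with `class`, `date`, `mean_ndvi`, `n`.
#' @export
class_trajectories <- function(zones, stack) {
  stopifnot(inherits(zones, "zone_map"), inherits(stack, "grid_stack"))
  if (!all(dim(zones$labels) == dim(stack$grids[[1]]$values)))
    stop("zone map and stack are not co-registered")
  lab <- zones$labels[zones$labels > 0]
  cls <- sort(unique(lab))
  rows <- lapply(seq_along(stack$grids), function(i) {
    v <- stack$grids[[i]]$values[zones$labels > 0]
    ok <- !is.na(v)
    mn <- tapply(v[ok], lab[ok], mean)
    nn <- tapply(v[ok], lab[ok], length)
    if (any(!cls %in% names(mn))) stop("empty class in trajectory computation")
    data.frame(class = cls, date = stack$dates[i],
               mean_ndvi = as.numeric(mn[as.character(cls)]),
               n = as.integer(nn[as.character(cls)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group fine classes into ranked zones
#'
#' Replaces expert grouping with a reproducible rule: fine classes are ranked
#' by their class-mean seasonal NDVI sum (the sum over dates of the per-class
#' mean NDVI) and cut into `n_groups` equal-rank tiers, so group 1 collects
#' the lowest-trajectory classes and group `n_groups` the highest. Ties in
#' class means are broken by class index.
#'
#' @param zones a fine-class [kmeans_stack()] result.
#' @param stack the co-registered [grid_stack()].
#' @param n_groups number of groups (at most the number of nonempty classes).
#' @return a grouped `zone_map` whose `legend` maps fine class to group.
#' @export
group_classes <- function(zones, stack, n_groups = 3) {
  stopifnot(inherits(zones, "zone_map"))
  traj <- class_trajectories(zones, stack)
  sums <- tapply(traj$mean_ndvi, traj$class, sum)
  cls <- as.integer(names(sums))
  ncls <- length(cls)
  if (n_groups > ncls) stop("n_groups exceeds the number of nonempty classes")
  ord <- order(sums, cls)                        # ties broken by class index
  tier <- integer(ncls)
  tier[ord] <- ceiling(seq_len(ncls) * n_groups / ncls)
  legend <- stats::setNames(tier, cls)
  labels <- zones$labels
  pos <- labels > 0
  labels[pos] <- tier[match(labels[pos], cls)]
  structure(list(labels = labels, k = n_groups, centers = NULL,
                 tot_withinss = zones$tot_withinss, grouped = TRUE,
                 legend = legend),
            class = "zone_map")
}
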