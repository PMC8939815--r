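# End-to-end demonstration pipeline on a synthetic season.

#' Preset harvester model for the synthetic season
#'
#' Linear yield and grain-protein models over the four preset dates:
#' yield responds positively to NDVI on every date (strongest early), while
#' grain protein combines a positive early-season and late-season response
#' with a negative mid-June term, as expected where early vigor and
#' grain-filling stress pull protein in opposite directions. Noise is set via
#' true-model R-squared targets (defaults 0.26 for yield, 0.40 for protein).
#'
#' @param seed integer seed.
#' @param target_r2_yield,target_r2_gpc true-model R-squared targets.
#' @return a [harvest_spec()] for a four-date stack.
#' @export
wheat_harvest_spec <- function(seed = 1, target_r2_yield = 0.26,
                                       target_r2_gpc = 0.40) {
  harvest_spec(
    yield_coefficients = c(-11520, 8617, 7254, 963.2, 3750),
    gpc_coefficients = c(-25.20, 52.36, -19.41, 0, 27.91),
    swath_width = 12, point_spacing = 1,
    target_r2_yield = target_r2_yield, target_r2_gpc = target_r2_gpc,
    seed = seed)
}

#' Run the full information-scaling pipeline on a synthetic season
#'
#' Simulates a coherent multi-date field, writes the per-date rasters,
#' co-registers them, interpolates to daily grids, builds the seasonal NDVI
#' sums, computes per-date scale profiles and Kullback-Leibler curves, radial
#' power spectra with power-law fits and break detection, simulates a
#' harvester run and performs per-date and all-subsets model selection for
#' yield and protein, and classifies the field into ranked zones. All outputs
#' are plain text (ESRI ASCII rasters, CSV tables, JSON summaries) under
#' `out_dir`; everything is deterministic given `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every random component.
#' @param shape grid dimensions of the simulated field.
#' @param pixel_size pixel size in metres.
#' @param k fine classes for the zoning step.
#' @param restarts k-means restarts.
#' @return invisibly, a list with the main result objects and `files`, the
#'   vector of paths written.
#' @export
run_info_pipeline <- function(out_dir, seed = 1, shape = c(256, 256),
                              pixel_size = 0.25, k = 50, restarts = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  files <- character(0)
  put <- function(p) { files <<- c(files, p); p }

  fs <- wheat_season_spec(shape = shape, pixel_size = pixel_size, seed = seed)
  season <- synthesize_season(fs)
  for (i in seq_along(season$grids))
    write_grid(season$grids[[i]],
               put(path(sprintf("ndvi_day%03d.asc", season$dates[i]))))

  stack <- resample_to_coarsest(season$grids)
  daily <- interpolate_daily(stack)
  sum_obs <- sum_stack(stack)
  sum_int <- sum_stack(daily)
  write_grid(sum_obs, put(path("sum_ndvi.asc")))
  write_grid(sum_int, put(path("sum_ndvi_int.asc")))

  targets <- c(12, 30)
  profiles <- do.call(rbind, lapply(seq_along(stack$grids), function(i) {
    pr <- scale_profile(stack$grids[[i]],
                        scale_factor_ladder(stack$grids[[i]], targets))
    cbind(date = stack$dates[i], as.data.frame(pr))
  }))
  utils::write.csv(profiles, put(path("scale_profiles.csv")), row.names = FALSE)

  kl <- do.call(rbind, lapply(seq_along(stack$grids), function(i) {
    cv <- kl_scale_curve(stack$grids[[i]],
                         scale_factor_ladder(stack$grids[[i]], targets))
    cbind(date = stack$dates[i], as.data.frame(cv))
  }))
  utils::write.csv(kl, put(path("kl_curves.csv")), row.names = FALSE)

  nyq <- 1 / (2 * pixel_size)
  ranges <- list(c(0, nyq / 4), c(nyq / 2, Inf))
  spectra <- do.call(rbind, lapply(seq_along(stack$grids), function(i) {
    sp <- radial_psd(stack$grids[[i]])
    cbind(date = stack$dates[i], as.data.frame(sp))
  }))
  utils::write.csv(spectra, put(path("spectra.csv")), row.names = FALSE)
  rep <- spectral_report(stack, ranges = ranges)
  jsonlite::write_json(
    list(fits = rep, breaks = attr(rep, "breaks")),
    put(path("spectral_fits.json")), dataframe = "rows", digits = NA,
    na = "null")

  hs <- wheat_harvest_spec(seed = seed)
  harvest <- synthesize_harvest(stack, hs)
  sums_at_points <- extract_buffer_means(
    list(sum_ndvi = sum_obs, sum_ndvi_int = sum_int),
    harvest[, c("x", "y", "pass", "heading")],
    width = hs$swath_width, along = hs$point_spacing)
  harvest$sum_ndvi_int <- sums_at_points$sum_ndvi_int
  utils::write.csv(harvest, put(path("harvest.csv")), row.names = FALSE)

  ndvi_cols <- paste0("ndvi_", stack$dates)
  excl <- list(sum_ndvi = c(ndvi_cols, "sum_ndvi_int"),
               sum_ndvi_int = c(ndvi_cols, "sum_ndvi"))
  preds <- harvest[, c(ndvi_cols, "sum_ndvi", "sum_ndvi_int")]
  sel_yield <- all_subsets_lm(harvest$yield, preds, exclusive = excl)
  sel_gpc <- all_subsets_lm(harvest$gpc, preds, exclusive = excl)
  utils::write.csv(sel_yield$models, put(path("yield_models.csv")),
                   row.names = FALSE)
  utils::write.csv(sel_gpc$models, put(path("gpc_models.csv")),
                   row.names = FALSE)
  simple <- rbind(cbind(response = "yield",
                        per_date_regressions(harvest, "yield", ndvi_cols)),
                  cbind(response = "gpc",
                        per_date_regressions(harvest, "gpc", ndvi_cols)))
  utils::write.csv(simple, put(path("per_date_regressions.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(yield_best = sel_yield$models$model[1],
         yield_best_weight = sel_yield$models$weight[1],
         gpc_best = sel_gpc$models$model[1],
         gpc_best_weight = sel_gpc$models$weight[1],
         n = sel_yield$n),
    put(path("model_selection.json")), auto_unbox = TRUE, digits = NA)

  zones <- kmeans_stack(stack, k = k, seed = seed, restarts = restarts)
  grouped <- group_classes(zones, stack, n_groups = 3)
  zone_grid <- ndvi_grid(matrix(as.numeric(grouped$labels), nrow(grouped$labels)),
                         pixel_size = stack$grids[[1]]$pixel_size,
                         origin = stack$grids[[1]]$origin, range = NULL)
  write_grid(zone_grid, put(path("zones.asc")), nodata = -1)
  utils::write.csv(class_trajectories(grouped, stack),
                   put(path("zone_trajectories.csv")), row.names = FALSE)

  invisible(list(field_spec = fs, stack = stack, harvest = harvest,
                 selection = list(yield = sel_yield, gpc = sel_gpc),
                 spectral = rep, zones = grouped, files = files))
}
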