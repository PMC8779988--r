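# The end-to-end delineation pipeline: (0) kriging to the common grid when
# the input is point samples, (1) range normalization, (2) correlation-based
# feature selection, (3) clustering, (4) island smoothing — plus the
# 21-scenario evaluation runner.

#' Pipeline configuration
#'
#' Defaults follow the recommended recipe: scenario `kmeans-nc-dec` with
#' k = 4 zones — coordinates excluded because kriging already encoded the
#' spatial correlation, features decreased at |r| > 0.7.
#'
#' @param scenario scenario name or `scenario_spec`.
#' @param k number of zones (k-means, FCM, hierarchical).
#' @param seed RNG seed; a run is fully reproducible from config + seed.
#' @param threshold feature-selection |r| cutoff.
#' @param priority feature priority order (most important first); default
#'   puts CEC first when present, then stack layer order.
#' @param cell_size common grid cell size, meters.
#' @param mask_radius kriging mask radius, meters (cells farther than this
#'   from every sample are outside the field).
#' @param neighborhood kriging neighborhood size (nearest points per cell).
#' @param variogram_family,n_lags,max_lag semivariogram settings.
#' @param island_size smoothing threshold in cells.
#' @param smoothing_eps,smoothing_min_pts,max_passes smoothing DBSCAN
#'   settings (`NULL` eps = 8-connectivity for the grid).
#' @param fcm_m FCM fuzziness.
#' @param h,quantile mean-shift bandwidth (explicit or estimated).
#' @param eps,min_pts DBSCAN clustering parameters; `NULL` eps defaults to
#'   the mean spatial scanning resolution of the grid (the cell size).
#' @param linkage hierarchical linkage.
#' @param n_restarts,max_iter,tol iteration controls.
#' @param vri_attrs attributes averaged into the VRI; default all layers.
#' @export
casp_config <- function(scenario = "kmeans-nc-dec", k = 4L, seed = 1L,
                        threshold = 0.7, priority = NULL,
                        cell_size = 5, mask_radius = 24, neighborhood = 32,
                        variogram_family = "spherical", n_lags = 15,
                        max_lag = NULL,
                        island_size = 5L, smoothing_eps = NULL,
                        smoothing_min_pts = 3L, max_passes = 10L,
                        fcm_m = 2, h = NULL, quantile = 0.3,
                        eps = NULL, min_pts = 3L, linkage = "single",
                        n_restarts = 10L, max_iter = 300L, tol = 1e-6,
                        vri_attrs = NULL) {
  structure(as.list(environment()), class = "casp_config")
}

#' Grid geometry covering a point set's bounding box
#' @param points a [point_samples].
#' @param cell_size cell size in meters.
#' @export
derive_geometry <- function(points, cell_size = 5) {
  x0 <- floor(min(points$x) / cell_size) * cell_size
  y0 <- floor(min(points$y) / cell_size) * cell_size
  grid_geometry(c(x0, y0), cell_size,
                ncols = max(1L, ceiling((max(points$x) - x0) / cell_size)),
                nrows = max(1L, ceiling((max(points$y) - y0) / cell_size)))
}

default_priority <- function(stack, priority) {
  if (!is.null(priority)) return(priority)
  nms <- names(stack$layers)
  c(intersect("CEC", nms), setdiff(nms, "CEC"))
}

#' Run the clustering-and-smoothing pipeline on one field
#'
#' Executes, in order: kriging of point samples onto the common grid (only
#' when `points` is given), range normalization, cross-correlation feature
#' selection, clustering, and island smoothing, per the configured
#' scenario. Validity metrics are computed on the clustering feature space
#' (DBI, Silhouette) and the raw attribute rasters (VRI).
#'
#' @param points a [point_samples] input (mode "points"), or `NULL`.
#' @param stack an `attribute_stack` input (mode "rasters"), or `NULL`.
#' @param config a [casp_config].
#' @param geom grid geometry for kriging; default derived from the sample
#'   bounding box at `config$cell_size`.
#' @param out_dir optional directory: writes `labels_raw.asc`,
#'   `labels_smoothed.asc`, `validity.tsv`, `selection.txt`,
#'   `smoothing_audit.csv` and `run_log.json`.
#' @return list: `stack`, `features`, `selection`, `model`, `raw_labels`,
#'   `smoothed` (list from [smooth_labels]), `validity`, `scenario`, `log`.
#' @export
run_casp <- function(points = NULL, stack = NULL, config = casp_config(),
                     geom = NULL, out_dir = NULL) {
  if (is.null(points) == is.null(stack))
    stop("give exactly one of `points` or `stack`")
  scenario <- if (is.character(config$scenario)) parse_scenario(config$scenario)
              else config$scenario
  stage <- "kriging"
  out <- tryCatch({
    if (!is.null(points)) {
      if (is.null(geom)) geom <- derive_geometry(points, config$cell_size)
      stack <- points_to_stack(points, geom,
                               neighborhood = config$neighborhood,
                               mask_radius = config$mask_radius,
                               n_lags = config$n_lags,
                               max_lag = config$max_lag,
                               family = config$variogram_family)
    }
    priority <- default_priority(stack, config$priority)
    stage <- "preprocessing"
    X <- build_feature_matrix(stack, scenario, priority = priority,
                              threshold = config$threshold)
    stage <- "clustering"
    algo_cfg <- config
    if (is.null(algo_cfg$eps)) algo_cfg$eps <- stack$cell_size
    model <- run_algorithm(X, scenario$algorithm, algo_cfg)
    lab_m <- matrix(NA_integer_, stack$nrows, stack$ncols)
    lab_m[attr(X, "cells")] <- model$labels
    raw_labels <- label_raster(lab_m, stack$origin, stack$cell_size)
    stage <- "validity"
    validity <- validity_report(X, model$labels, stack, config$vri_attrs)
    stage <- "smoothing"
    sm_spec <- smoothing_spec(island_size = config$island_size,
                              eps = config$smoothing_eps,
                              min_pts = config$smoothing_min_pts,
                              max_passes = config$max_passes,
                              cell_size = stack$cell_size)
    smoothed <- smooth_labels(raw_labels, sm_spec)
    log <- list(scenario = scenario$name, seed = config$seed,
                k = config$k, threshold = config$threshold,
                priority = priority,
                island_size = sm_spec$island_size,
                smoothing_eps = sm_spec$eps,
                n_cells = sum(stack$mask),
                n_clusters = validity$n_clusters_effective,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    list(stack = stack, features = X, selection = attr(X, "selection"),
         model = model, raw_labels = raw_labels, smoothed = smoothed,
         validity = validity, scenario = scenario, log = log)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ascii_grid(labels_as_layer(out$raw_labels),
                     file.path(out_dir, "labels_raw.asc"))
    write_ascii_grid(labels_as_layer(out$smoothed$labels),
                     file.path(out_dir, "labels_smoothed.asc"))
    v <- out$validity
    utils::write.table(
      data.frame(metric = c("dbi", "silhouette", "vri_mean"),
                 value = c(v$dbi, v$silhouette, v$vri_mean)),
      file.path(out_dir, "validity.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    if (!is.null(out$selection)) {
      sel <- out$selection
      writeLines(c(paste("kept:", paste(sel$kept, collapse = ", ")),
                   paste("removed:", paste(sel$removed, collapse = ", "))),
                 file.path(out_dir, "selection.txt"))
    }
    utils::write.csv(out$smoothed$audit,
                     file.path(out_dir, "smoothing_audit.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Run the scenario grid and produce the evaluation table
#'
#' Evaluates each scenario on the field with [evaluate_scenarios] (one row
#' per scenario: DBI, Silhouette, mean VRI, or n.v.). Smoothing is applied
#' only for the single chosen scenario via [run_casp], not here.
#'
#' @param stack an `attribute_stack`.
#' @param scenarios scenario list; default the full 21-scenario grid.
#' @param config a [casp_config].
#' @return the report data frame.
#' @export
run_scenarios <- function(stack, scenarios = default_scenarios(),
                          config = casp_config()) {
  if (!length(scenarios))
    return(evaluate_scenarios(stack, list(), list()))
  cfg <- unclass(config)
  cfg$priority <- default_priority(stack, config$priority)
  if (is.null(cfg$eps)) cfg$eps <- stack$cell_size
  evaluate_scenarios(stack, scenarios, cfg)
}
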