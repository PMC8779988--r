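# Density-based smoothing of zone maps: detects small disconnected parts of
# a cluster ("islands") with a spatial DBSCAN over each cluster's cell
# centers and relabels them by majority vote of the labels adjacent to the
# island's edge cells, so the zone map is actuatable by variable-rate
# machinery.

#' Smoothing parameters
#'
#' @param island_size components with fewer cells than this are islands and
#'   get relabeled.
#' @param eps spatial DBSCAN radius, meters; the default
#'   `cell_size * sqrt(2) + 1e-6` makes components equal 8-connected regions
#'   on the grid.
#' @param min_pts DBSCAN core threshold (including the cell itself).
#' @param max_passes iteration cap; relabeling can create new sub-threshold
#'   fragments, so passes repeat until a fixed point.
#' @param neighbor_radius voting radius for edge-cell neighbors, meters;
#'   default `eps`.
#' @param cell_size grid cell size used for the eps default.
#' @export
smoothing_spec <- function(island_size = 5L, eps = NULL, min_pts = 3L,
                           max_passes = 10L, neighbor_radius = NULL,
                           cell_size = 5) {
  if (island_size < 1L) stop("island_size must be >= 1")
  if (is.null(eps)) eps <- cell_size * sqrt(2) + 1e-6
  if (eps <= 0) stop("eps must be > 0")
  if (min_pts < 1L) stop("min_pts must be >= 1")
  if (is.null(neighbor_radius)) neighbor_radius <- eps
  structure(list(island_size = as.integer(island_size), eps = eps,
                 min_pts = as.integer(min_pts),
                 max_passes = as.integer(max_passes),
                 neighbor_radius = neighbor_radius),
            class = "smoothing_spec")
}

#' Convert an island area in square meters to a cell-count threshold
#'
#' Variable-rate actuators cannot respond to zones smaller than the active
#' control unit; this maps that physical size onto the grid.
#'
#' @param area_m2 smallest actuatable area, square meters.
#' @param cell_size grid cell size, meters.
#' @export
island_size_from_area <- function(area_m2, cell_size) {
  as.integer(ceiling(area_m2 / cell_size^2))
}

#' Spatial components of one cluster's cells
#'
#' Runs DBSCAN on the cell-center coordinates of the cells carrying
#' `cluster_label` only. With the default eps this partitions the cluster
#' into its 8-connected parts; low-density cells come back as outliers.
#'
#' @param labels a `label_raster`.
#' @param cluster_label the cluster to decompose.
#' @param eps,min_pts spatial DBSCAN parameters.
#' @return list with `components` (list of raster cell-index vectors, in
#'   discovery order) and `outliers` (cell indices).
#' @export
find_components <- function(labels, cluster_label, eps, min_pts = 3L) {
  cells <- which(!is.na(labels$values) & labels$values == cluster_label)
  if (!length(cells)) return(list(components = list(), outliers = integer(0)))
  if (length(cells) == 1L) {
    # a lone cell is core iff min_pts == 1
    if (min_pts <= 1L)
      return(list(components = list(cells), outliers = integer(0)))
    return(list(components = list(), outliers = cells))
  }
  ctr <- cell_centers(labels, cells)
  db <- cluster_dbscan(ctr, eps = eps, min_pts = min_pts)
  comps <- lapply(seq_len(db$k) - 1L, function(j) cells[db$labels == j])
  list(components = comps, outliers = cells[db$labels == -1L])
}

# nearest non-outlier assignment; ties on distance go to the lowest label
nearest_label <- function(labels, from_cells, pool_cells, tol = 1e-9) {
  pc <- cell_centers(labels, pool_cells)
  fc <- cell_centers(labels, from_cells)
  pool_lab <- labels$values[pool_cells]
  out <- integer(length(from_cells))
  for (i in seq_along(from_cells)) {
    d2 <- (pc[, 1] - fc[i, 1])^2 + (pc[, 2] - fc[i, 2])^2
    near <- d2 <= min(d2) + tol
    out[i] <- min(pool_lab[near])
  }
  out
}

#' Reassign spatial-outlier cells to their nearest neighbor's cluster
#'
#' Each outlier cell takes the current label of the nearest non-outlier
#' in-mask cell (Euclidean distance between cell centers); exact distance
#' ties resolve to the lowest label.
#'
#' @param labels a `label_raster`.
#' @param outlier_cells raster cell indices to reassign.
#' @return the updated `label_raster`.
#' @export
reassign_outliers <- function(labels, outlier_cells) {
  if (!length(outlier_cells)) return(labels)
  pool <- setdiff(which(!is.na(labels$values)), outlier_cells)
  if (!length(pool)) stop("no non-outlier cells to reassign to")
  labels$values[outlier_cells] <-
    nearest_label(labels, outlier_cells, pool)
  labels
}

#' Relabel one island by the majority vote of its edge neighbors
#'
#' Edge cells are island cells with at least one in-mask neighbor within
#' `neighbor_radius` outside the island; every such outside neighbor votes
#' once per adjacency (multiplicity weights longer shared borders). The
#' whole island takes the plurality label; vote ties resolve to the lowest
#' label. An island with no outside neighbors is left unchanged with a
#' warning.
#'
#' @param labels a `label_raster`.
#' @param island_cells raster cell indices of the island.
#' @param neighbor_radius voting radius in meters.
#' @return list `labels` (updated raster) and `record` (an audit row:
#'   cluster_label, size, edge cell count, vote tally, assigned label).
#' @export
relabel_island <- function(labels, island_cells, neighbor_radius) {
  own <- labels$values[island_cells[1L]]
  inmask <- which(!is.na(labels$values))
  outside <- setdiff(inmask, island_cells)
  ic <- cell_centers(labels, island_cells)
  oc <- cell_centers(labels, outside)
  r2 <- neighbor_radius^2 + 1e-9
  votes <- integer(0)
  edge <- integer(0)
  for (i in seq_along(island_cells)) {
    d2 <- (oc[, 1] - ic[i, 1])^2 + (oc[, 2] - ic[i, 2])^2
    nb <- outside[d2 <= r2]
    if (length(nb)) {
      edge <- c(edge, island_cells[i])
      votes <- c(votes, labels$values[nb])
    }
  }
  votes <- votes[votes >= 0L]
  if (!length(votes)) {
    warning("island with no outside neighbors left unchanged")
    return(list(labels = labels,
                record = list(cluster_label = own, size = length(island_cells),
                              n_edge = 0L, votes = table(integer(0)),
                              assigned_label = own)))
  }
  tally <- table(votes)
  winners <- as.integer(names(tally)[tally == max(tally)])
  new_lab <- min(winners)
  labels$values[island_cells] <- new_lab
  list(labels = labels,
       record = list(cluster_label = own, size = length(island_cells),
                     n_edge = length(edge), votes = tally,
                     assigned_label = new_lab))
}

#' Smooth a zone map by removing islands
#'
#' Per pass, for each cluster label in ascending order: decompose the
#' cluster into spatial components ([find_components]), reassign DBSCAN
#' outlier cells to their nearest neighbor's cluster, then relabel every
#' component smaller than `island_size` by edge-neighbor majority vote.
#' Passes repeat until nothing changes or `max_passes` is reached
#' (relabeling can expose new sub-threshold fragments). Any pre-existing
#' `-1` (clustering outlier) cells are first joined to their nearest
#' labeled cell.
#'
#' @param labels a `label_raster`.
#' @param spec a [smoothing_spec]; its eps default is recomputed from the
#'   raster's cell size when the spec was built with a different one.
#' @return list `labels` (smoothed raster), `audit` (data frame of island
#'   relabelings per pass), `island_cells` (cell indices per audit row),
#'   `outlier_cells` (all cells changed by outlier reassignment),
#'   `passes`, `converged`.
#' @export
smooth_labels <- function(labels, spec = smoothing_spec(cell_size = labels$cell_size)) {
  audit <- list()
  island_cells <- list()
  outlier_cells <- integer(0)
  pre <- which(!is.na(labels$values) & labels$values == -1L)
  if (length(pre)) {
    pool <- which(!is.na(labels$values) & labels$values >= 0L)
    if (!length(pool)) stop("no labeled cells: cannot smooth an all-outlier map")
    labels$values[pre] <- nearest_label(labels, pre, pool)
  }
  converged <- FALSE
  pass <- 0L
  while (pass < spec$max_passes) {
    pass <- pass + 1L
    changed <- FALSE
    for (lab in sort(unique(labels$values[!is.na(labels$values)]))) {
      fc <- find_components(labels, lab, spec$eps, spec$min_pts)
      if (length(fc$outliers)) {
        labels <- reassign_outliers(labels, fc$outliers)
        outlier_cells <- c(outlier_cells, fc$outliers)
        changed <- TRUE
      }
      for (comp in fc$components) {
        if (length(comp) >= spec$island_size) next
        # component may have been annexed by an earlier relabel this pass
        if (!all(labels$values[comp] == lab)) next
        res <- relabel_island(labels, comp, spec$neighbor_radius)
        labels <- res$labels
        if (res$record$assigned_label != lab) {
          changed <- TRUE
          audit[[length(audit) + 1L]] <-
            data.frame(pass = pass, cluster_label = res$record$cluster_label,
                       size = res$record$size, n_edge = res$record$n_edge,
                       assigned_label = res$record$assigned_label)
          island_cells[[length(audit)]] <- comp
        }
      }
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning("smoothing did not reach a fixed point within max_passes = ",
            spec$max_passes)
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(pass = integer(0), cluster_label = integer(0),
               size = integer(0), n_edge = integer(0),
               assigned_label = integer(0))
  list(labels = labels, audit = audit, island_cells = island_cells,
       outlier_cells = unique(c(pre, outlier_cells)), passes = pass,
       converged = converged)
}
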