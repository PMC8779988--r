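# Semivariogram estimation/fitting and ordinary kriging of point samples
# onto the common grid. Weights solve the ordinary-kriging system with the
# sum-to-one (unbiasedness) constraint via a Lagrange multiplier.

#' Semivariogram model value
#'
#' Evaluates gamma(h) for a fitted model. All families share the
#' parameterization `nugget + partial_sill * f(h / range)` with
#' `gamma(0) = 0` exactly (the nugget is a discontinuity at the origin).
#'
#' @param model a `variogram_model`.
#' @param h separation distances in meters.
#' @export
variogram_gamma <- function(model, h) {
  h <- as.numeric(h)
  g <- numeric(length(h))
  pos <- h > 0
  hr <- h[pos] / model$range_m
  s <- switch(model$family,
    spherical  = ifelse(hr >= 1, 1, 1.5 * hr - 0.5 * hr^3),
    exponential = 1 - exp(-3 * hr),
    gaussian   = 1 - exp(-3 * hr^2),
    stop("unknown variogram family: ", model$family))
  g[pos] <- model$nugget + model$partial_sill * s
  g
}

#' Create a semivariogram model
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget nugget variance, `>= 0` (attribute units squared).
#' @param partial_sill sill minus nugget, `>= 0`.
#' @param range_m range parameter in meters, `> 0`. For the exponential and
#'   gaussian families this is the practical range (95% of the sill).
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, partial_sill, range_m) {
  family <- match.arg(family)
  if (nugget < 0 || partial_sill < 0 || range_m <= 0)
    stop("invalid variogram parameters: need nugget, partial_sill >= 0, range > 0")
  structure(list(family = family, nugget = nugget,
                 partial_sill = partial_sill, range_m = range_m),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$family, x$nugget, x$partial_sill, x$range_m))
  invisible(x)
}

#' Empirical semivariogram
#'
#' Method-of-moments estimator: for each lag bin b,
#' `gamma_b = sum (z_i - z_j)^2 / (2 N_b)` over point pairs whose separation
#' falls in the bin. Empty bins are dropped.
#'
#' @param points a [point_samples] object.
#' @param attr attribute name.
#' @param n_lags number of equal-width lag bins.
#' @param max_lag maximum separation considered, meters; default half the
#'   maximum pairwise distance.
#' @return an `empirical_variogram` with `lag_centers`, `gamma`, `pair_counts`.
#' @export
empirical_semivariogram <- function(points, attr, n_lags = 15, max_lag = NULL) {
  if (points$n < 2L) stop("need at least two points")
  z <- points$attributes[[attr]]
  if (is.null(z)) stop("no attribute '", attr, "'")
  d <- as.vector(stats::dist(cbind(points$x, points$y)))
  if (max(d) == 0) stop("degenerate geometry: all points coincident")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (max_lag <= 0) stop("max_lag must be > 0")
  dz2 <- as.vector(stats::dist(z))^2
  keep <- d > 0 & d <= max_lag
  d <- d[keep]; dz2 <- dz2[keep]
  width <- max_lag / n_lags
  bin <- pmin(floor(d / width) + 1L, n_lags)
  counts <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags), function(b) sum(dz2[bin == b]), numeric(1))
  nonempty <- counts > 0L
  structure(list(lag_centers = (seq_len(n_lags)[nonempty] - 0.5) * width,
                 gamma = gsum[nonempty] / (2 * counts[nonempty]),
                 pair_counts = counts[nonempty],
                 max_lag = max_lag),
            class = "empirical_variogram")
}

#' Fit a semivariogram model by weighted least squares
#'
#' Minimizes `sum_b N_b (gamma_model(h_b) - gamma_b)^2` (weights = pair
#' counts) with bounds `nugget, partial_sill >= 0` and
#' `range in (0, 2 max_lag]`, using multi-start box-constrained
#' quasi-Newton optimization.
#'
#' @param emp an `empirical_variogram` with at least 3 non-empty bins.
#' @param family model family, default spherical.
#' @return a [variogram_model].
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  if (length(emp$gamma) < 3L)
    stop("need at least 3 non-empty lag bins to fit a variogram")
  h <- emp$lag_centers; g <- emp$gamma; w <- emp$pair_counts
  hi_range <- 2 * max(emp$max_lag, max(h))
  obj <- function(p) {
    m <- list(family = family, nugget = p[1], partial_sill = p[2], range_m = p[3])
    sum(w * (variogram_gamma(m, h) - g)^2)
  }
  sill0 <- max(g); nug0 <- max(min(g), 0)
  starts <- list(
    c(nug0, max(sill0 - nug0, 1e-8), max(h) / 2),
    c(0, max(sill0, 1e-8), max(h) / 3),
    c(sill0 / 2, max(sill0 / 2, 1e-8), max(h)),
    c(mean(g), 1e-8, max(h) / 2))            # near-pure-nugget start
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::nlminb(p0, obj, lower = c(0, 0, 1e-6 * hi_range),
                    upper = c(Inf, Inf, hi_range)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("variogram fit did not converge (", family, ", ",
         length(h), " bins)")
  variogram_model(family, best$par[1], best$par[2], best$par[3])
}

# Average z-values at duplicated coordinates; kriging matrices are singular
# otherwise.
dedup_points <- function(xy, z) {
  key <- paste(xy[, 1], xy[, 2], sep = "\r")
  if (!anyDuplicated(key)) return(list(xy = xy, z = z, had_dups = FALSE))
  agg_z <- tapply(z, key, mean)
  first <- !duplicated(key)
  ord <- key[first]
  list(xy = xy[first, , drop = FALSE], z = as.numeric(agg_z[ord]),
       had_dups = TRUE)
}

# Solve the OK system for one target given neighbor coordinates/values.
# Returns list(pred, weights). gamma(0) = 0 on the diagonal so prediction is
# exact at sample sites.
ok_solve <- function(nxy, nz, txy, vmodel) {
  m <- nrow(nxy)
  G <- matrix(0, m + 1L, m + 1L)
  D <- as.matrix(stats::dist(nxy))
  G[1:m, 1:m] <- variogram_gamma(vmodel, D)
  G[m + 1L, 1:m] <- 1; G[1:m, m + 1L] <- 1
  g0 <- variogram_gamma(vmodel,
                        sqrt((nxy[, 1] - txy[1])^2 + (nxy[, 2] - txy[2])^2))
  rhs <- c(g0, 1)
  sol <- tryCatch(solve(G, rhs), error = function(e) {
    # ridge on the point block as a last resort
    diag(G)[1:m] <- diag(G)[1:m] + 1e-10 * max(1, max(G))
    solve(G, rhs)
  })
  w <- sol[1:m]
  list(pred = sum(w * nz), weights = w, lagrange = sol[m + 1L])
}

#' Ordinary kriging of one attribute onto a grid
#'
#' Per target cell, solves the ordinary-kriging system over the
#' `neighborhood` nearest sample points with the unbiasedness constraint
#' (weights sum to 1) via a Lagrange multiplier; the prediction is the
#' weighted sum of neighbor values. Duplicate sample coordinates are
#' averaged first (with a warning).
#'
#' @param points a [point_samples] object.
#' @param attr attribute name.
#' @param vmodel a [variogram_model].
#' @param geom a `grid_geometry`.
#' @param neighborhood number of nearest points used per cell (`Inf` = all,
#'   the global system used by oracle tests).
#' @param mask optional logical matrix of cells to predict; default all.
#' @param return_weights if `TRUE`, also return the per-cell weight list
#'   (intended for tests; memory-heavy on large grids).
#' @return a [grid_layer] of predictions (attribute `weights` if requested).
#' @export
ordinary_krige <- function(points, attr, vmodel, geom, neighborhood = 32,
                           mask = NULL, return_weights = FALSE) {
  geom <- geometry_of(geom)
  if (!is.finite(neighborhood)) neighborhood <- points$n
  if (neighborhood < 2) stop("neighborhood must be >= 2")
  z <- points$attributes[[attr]]
  if (is.null(z)) stop("no attribute '", attr, "'")
  dd <- dedup_points(cbind(points$x, points$y), z)
  if (dd$had_dups)
    warning("duplicate sample coordinates averaged before kriging")
  xy <- dd$xy; z <- dd$z
  m <- min(neighborhood, nrow(xy))
  cells <- if (is.null(mask)) seq_len(geom$nrows * geom$ncols) else which(mask)
  ctr <- cell_centers(geom, cells)
  out <- matrix(NA_real_, geom$nrows, geom$ncols)
  wts <- if (return_weights) vector("list", length(cells)) else NULL
  for (i in seq_along(cells)) {
    d2 <- (xy[, 1] - ctr[i, 1])^2 + (xy[, 2] - ctr[i, 2])^2
    nb <- order(d2)[seq_len(m)]
    sol <- ok_solve(xy[nb, , drop = FALSE], z[nb], ctr[i, ], vmodel)
    out[cells[i]] <- sol$pred
    if (return_weights) wts[[i]] <- list(cells = nb, weights = sol$weights)
  }
  layer <- grid_layer(out, geom$origin, geom$cell_size)
  if (return_weights) attr(layer, "weights") <- wts
  layer
}

#' Krige several attributes onto a common grid
#'
#' Applies [ordinary_krige] per attribute. The field mask keeps only cells
#' whose center lies within `mask_radius` of at least one sample point,
#' bounding extrapolation between scanning transects.
#'
#' @inheritParams ordinary_krige
#' @param attrs attribute names; default all.
#' @param vmodels named list of [variogram_model]s (one per attribute), or a
#'   single model recycled, or `NULL` to fit a model per attribute from the
#'   empirical semivariogram.
#' @param mask_radius meters; default 24 (twice the usual 12 m inter-line
#'   spacing).
#' @param n_lags,max_lag forwarded to [empirical_semivariogram] when models
#'   are fitted here.
#' @param family variogram family used when fitting here.
#' @return an `attribute_stack`.
#' @export
points_to_stack <- function(points, geom, attrs = NULL, vmodels = NULL,
                            neighborhood = 32, mask_radius = 24,
                            n_lags = 15, max_lag = NULL,
                            family = "spherical") {
  geom <- geometry_of(geom)
  if (is.null(attrs)) attrs <- names(points$attributes)
  ctr <- cell_centers(geom)
  mask <- matrix(FALSE, geom$nrows, geom$ncols)
  # distance from each cell center to the nearest sample
  for (i in seq_len(geom$nrows * geom$ncols)) {
    d2 <- min((points$x - ctr[i, 1])^2 + (points$y - ctr[i, 2])^2)
    mask[i] <- d2 <= mask_radius^2
  }
  layers <- list()
  for (a in attrs) {
    vm <- if (inherits(vmodels, "variogram_model")) vmodels else vmodels[[a]]
    if (is.null(vm)) {
      emp <- empirical_semivariogram(points, a, n_lags = n_lags, max_lag = max_lag)
      vm <- fit_variogram(emp, family)
    }
    layers[[a]] <- ordinary_krige(points, a, vm, geom,
                                  neighborhood = neighborhood, mask = mask)
  }
  stack_layers(layers)
}
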