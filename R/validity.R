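# Cluster validity indices: Davies-Bouldin, Silhouette, and the variance
# reduction index (VRI). Outliers (label -1) are excluded from all three;
# DBI and Silhouette are undefined ("n.v.") with fewer than two effective
# clusters and then return NA rather than erroring.

drop_outliers <- function(X, labels) {
  keep <- labels >= 0
  list(X = X[keep, , drop = FALSE], labels = labels[keep], n_out = sum(!keep))
}

#' Davies-Bouldin index
#'
#' `DBI = (1/k) sum_i max_{j != i} (s_i + s_j) / d_ij` where `s_i` is the
#' mean Euclidean distance of cluster i members to their centroid (the
#' arithmetic mean) and `d_ij` the distance between centroids. Lower is
#' better. Returns `NA` (the "n.v." convention) when fewer than two
#' non-outlier clusters exist.
#'
#' @param X numeric feature matrix.
#' @param labels integer labels (`-1` = outlier, excluded).
#' @export
davies_bouldin <- function(X, labels) {
  d <- drop_outliers(as.matrix(X), labels)
  ids <- sort(unique(d$labels))
  k <- length(ids)
  if (k < 2L) return(NA_real_)
  C <- matrix(0, k, ncol(d$X))
  for (jj in seq_len(k))
    C[jj, ] <- colMeans(d$X[d$labels == ids[jj], , drop = FALSE])
  s <- vapply(seq_along(ids), function(jj) {
    M <- d$X[d$labels == ids[jj], , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2L, C[jj, ])^2)))
  }, numeric(1))
  Dc <- as.matrix(stats::dist(C))
  R <- outer(s, s, `+`) / Dc
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Silhouette index
#'
#' Per point: `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean
#' distance to the other members of its own cluster and `b(i)` the smallest
#' mean distance to another cluster. Members of singleton clusters get
#' `s(i) = 0`. The overall index is the mean over non-outlier points; `NA`
#' when fewer than two clusters exist.
#'
#' @inheritParams davies_bouldin
#' @export
silhouette_index <- function(X, labels) {
  d <- drop_outliers(as.matrix(X), labels)
  ids <- sort(unique(d$labels))
  k <- length(ids)
  if (k < 2L) return(NA_real_)
  n <- nrow(d$X)
  D <- as.matrix(stats::dist(d$X))
  # mean distance from every point to every cluster
  sums <- t(rowsum(t(D), d$labels))          # n x k, columns sorted by id
  cnt <- as.integer(table(factor(d$labels, levels = ids)))
  own <- match(d$labels, ids)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- own[i]
    if (cnt[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (cnt[ci] - 1L)        # exclude self (d(i,i)=0)
    b <- min(sums[i, -ci] / cnt[-ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Variance reduction index
#'
#' For attribute theta: `VRI = (1 - sum_i A_i v_i / v) * 100` with `A_i`
#' the area fraction of cluster i (cell count over in-mask cell count),
#' `v_i` its within-cluster variance and `v` the whole-field variance —
#' population (1/N) variances throughout, computed on the RAW attribute
#' rasters, never on normalized features. Outlier cells are excluded from
#' both the fractions and the variances. Higher is better; a single cluster
#' gives exactly 0; a zero-variance attribute is skipped with a warning.
#'
#' @param stack an `attribute_stack` of raw attribute values.
#' @param labels a `label_raster` on the same geometry, or an integer vector
#'   aligned to the in-mask cells of `stack` (canonical column-major order).
#' @param attrs attribute names to score; default all layers.
#' @return list with `per_attribute` (named vector, percent) and `mean`.
#' @export
vri <- function(stack, labels, attrs = NULL) {
  if (is.null(attrs)) attrs <- names(stack$layers)
  cells <- mask_cells(stack)
  lab <- if (inherits(labels, "label_raster")) {
    if (!same_geometry(labels, stack))
      stop("label raster is not aligned to the attribute stack")
    labels$values[cells]
  } else {
    if (length(labels) != length(cells))
      stop("labels must have one value per in-mask cell")
    as.integer(labels)
  }
  keep <- !is.na(lab) & lab >= 0L
  lab <- lab[keep]
  if (!length(lab)) stop("no non-outlier labeled cells")
  A <- as.numeric(table(lab)) / length(lab)
  ids <- sort(unique(lab))
  pop_var <- function(v) mean((v - mean(v))^2)
  per <- vapply(attrs, function(a) {
    z <- stack$layers[[a]][cells][keep]
    v <- pop_var(z)
    if (v == 0) return(NA_real_)
    within <- vapply(ids, function(j) pop_var(z[lab == j]), numeric(1))
    (1 - sum(A * within) / v) * 100
  }, numeric(1))
  if (anyNA(per))
    warning("zero-variance attribute(s) skipped: ",
            paste(attrs[is.na(per)], collapse = ", "))
  list(per_attribute = per, mean = mean(per, na.rm = TRUE))
}

#' Score a labeling with all three validity metrics
#'
#' @param X the feature matrix the clustering ran on (distances for DBI and
#'   Silhouette are measured in this space).
#' @param labels integer labels aligned to rows of `X`.
#' @param stack raw attribute stack for VRI; `NULL` skips VRI.
#' @param attrs attributes entering the VRI mean.
#' @return a `validity_report`: `dbi`, `silhouette`, `vri_per_attribute`,
#'   `vri_mean`, `n_clusters_effective`, `n_outliers_excluded`.
#' @export
validity_report <- function(X, labels, stack = NULL, attrs = NULL) {
  eff <- sort(unique(labels[labels >= 0]))
  v <- if (!is.null(stack)) vri(stack, labels, attrs) else
    list(per_attribute = NULL, mean = NA_real_)
  structure(list(dbi = davies_bouldin(X, labels),
                 silhouette = silhouette_index(X, labels),
                 vri_per_attribute = v$per_attribute,
                 vri_mean = v$mean,
                 n_clusters_effective = length(eff),
                 n_outliers_excluded = sum(labels == -1L)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n.v." else sprintf("%.4g", v)
  cat(sprintf("<validity_report> DBI %s, Silhouette %s, mean VRI %s%% (%d clusters, %d outliers)\n",
              fmt(x$dbi), fmt(x$silhouette), fmt(x$vri_mean),
              x$n_clusters_effective, x$n_outliers_excluded))
  invisible(x)
}

#' Evaluate a list of scenarios on one field
#'
#' Builds the scenario feature matrix, runs the scenario's algorithm, and
#' scores the labeling with DBI, Silhouette and mean VRI (always on the raw
#' attribute stack). A failing scenario yields an error row, not a crash.
#'
#' @param stack raw `attribute_stack`.
#' @param scenarios list of `scenario_spec` (or names); default the full
#'   21-scenario grid.
#' @param config algorithm parameters forwarded to [run_algorithm], plus
#'   `priority` / `threshold` for feature selection and `vri_attrs`.
#' @return data frame: scenario, algorithm, n_clusters, n_outliers, dbi,
#'   silhouette, vri (NA = "n.v."), error.
#' @export
evaluate_scenarios <- function(stack, scenarios = default_scenarios(),
                               config = list()) {
  rows <- lapply(scenarios, function(sc) {
    if (is.character(sc)) sc <- parse_scenario(sc)
    res <- tryCatch({
      X <- build_feature_matrix(stack, sc, priority = config$priority,
                                threshold = config$threshold %||% 0.7)
      model <- run_algorithm(X, sc$algorithm, config)
      rep <- validity_report(X, model$labels, stack, config$vri_attrs)
      data.frame(scenario = sc$name, algorithm = sc$algorithm,
                 n_clusters = rep$n_clusters_effective,
                 n_outliers = rep$n_outliers_excluded,
                 dbi = rep$dbi, silhouette = rep$silhouette,
                 vri = rep$vri_mean, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(scenario = sc$name, algorithm = sc$algorithm,
                 n_clusters = NA_integer_, n_outliers = NA_integer_,
                 dbi = NA_real_, silhouette = NA_real_, vri = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  if (!length(rows))
    return(data.frame(scenario = character(0), algorithm = character(0),
                      n_clusters = integer(0), n_outliers = integer(0),
                      dbi = numeric(0), silhouette = numeric(0),
                      vri = numeric(0), error = character(0)))
  do.call(rbind, rows)
}

#' Write a scenario report as delimited text ("n.v." for undefined metrics)
#'
#' @param report data frame from [evaluate_scenarios].
#' @param path output path.
#' @param sep field separator.
#' @export
write_scenario_report <- function(report, path, sep = "\t") {
  out <- report
  for (cc in c("dbi", "silhouette", "vri")) {
    v <- out[[cc]]
    out[[cc]] <- ifelse(is.na(v), "n.v.", formatC(v, format = "g", digits = 6))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
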