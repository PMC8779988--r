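# Range normalization, Pearson cross-correlation feature selection, scenario
# grammar, and feature-matrix assembly.

#' Define a clustering scenario
#'
#' Scenarios combine an algorithm with three input-data conditions:
#' range normalization on/off, xy coordinate columns on/off, and
#' correlation-based feature decrease on/off. The canonical name grammar is
#' `<algorithm>-<tokens>`: `nn-nc` (no normalization, no coordinates),
#' `wn-nc`, `wn-wc`, `nc-dec`, `wc-dec` — normalization is implied on in
#' every scenario except the single `nn` one, which is only defined for
#' k-means.
#'
#' @param algorithm one of `"kmeans"`, `"fcm"`, `"meanshift"`,
#'   `"hierarchical"`, `"dbscan"`.
#' @param normalize apply range normalization?
#' @param include_coords append (and, when normalizing, normalize) the cell
#'   center x/y columns?
#' @param feature_decrease apply correlation-based feature selection?
#' @return a `scenario_spec` with a derived `name`.
#' @export
scenario_spec <- function(algorithm = c("kmeans", "fcm", "meanshift",
                                        "hierarchical", "dbscan"),
                          normalize = TRUE, include_coords = FALSE,
                          feature_decrease = FALSE) {
  algorithm <- match.arg(algorithm)
  if (!normalize && algorithm != "kmeans")
    stop("the un-normalized scenario is only defined for kmeans")
  tokens <- if (!normalize) "nn-nc"
            else if (feature_decrease && include_coords) "wc-dec"
            else if (feature_decrease) "nc-dec"
            else if (include_coords) "wn-wc"
            else "wn-nc"
  structure(list(algorithm = algorithm, normalize = normalize,
                 include_coords = include_coords,
                 feature_decrease = feature_decrease,
                 name = paste0(algorithm, "-", tokens)),
            class = "scenario_spec")
}

#' Parse a scenario name like "kmeans-nc-dec"
#' @param name scenario name string.
#' @return a `scenario_spec`.
#' @export
parse_scenario <- function(name) {
  parts <- strsplit(tolower(name), "-")[[1]]
  if (length(parts) != 3L)
    stop("invalid scenario name: '", name, "'")
  alg <- switch(parts[1], kmeans = "kmeans", km = "kmeans", fcm = "fcm",
                ms = "meanshift", meanshift = "meanshift",
                hier = "hierarchical", hierarchical = "hierarchical",
                dbscan = "dbscan", dbs = "dbscan",
                stop("unknown algorithm in scenario name: '", parts[1], "'"))
  toks <- parts[2:3]
  ok_tokens <- list(c("nn", "nc"), c("wn", "nc"), c("wn", "wc"),
                    c("nc", "dec"), c("wc", "dec"))
  if (!any(vapply(ok_tokens, identical, logical(1), toks)))
    stop("invalid scenario condition tokens: '", paste(toks, collapse = "-"), "'")
  scenario_spec(alg,
                normalize = !"nn" %in% toks,
                include_coords = "wc" %in% toks,
                feature_decrease = "dec" %in% toks)
}

#' The full evaluation grid of 21 scenarios
#'
#' k-means runs all five input conditions (it is the only algorithm with an
#' un-normalized variant); the other four algorithms run the four normalized
#' conditions.
#' @return list of `scenario_spec`.
#' @export
default_scenarios <- function() {
  out <- list(scenario_spec("kmeans", normalize = FALSE))
  for (alg in c("kmeans", "fcm", "meanshift", "hierarchical", "dbscan")) {
    out <- c(out, list(
      scenario_spec(alg, include_coords = FALSE, feature_decrease = FALSE),
      scenario_spec(alg, include_coords = TRUE,  feature_decrease = FALSE),
      scenario_spec(alg, include_coords = FALSE, feature_decrease = TRUE),
      scenario_spec(alg, include_coords = TRUE,  feature_decrease = TRUE)))
  }
  out
}

#' Range-normalize a feature matrix to [0, 1]
#'
#' Per column: `(v - min) / (max - min)`. Constant columns map to all zeros
#' with a warning. The original per-column ranges are stored in attribute
#' `"ranges"` for inverse mapping.
#'
#' @param m numeric matrix with named columns.
#' @return the normalized matrix.
#' @export
range_normalize <- function(m) {
  if (!is.matrix(m) || !nrow(m) || !ncol(m)) stop("empty feature matrix")
  lo <- apply(m, 2L, min); hi <- apply(m, 2L, max)
  span <- hi - lo
  const <- span == 0
  if (any(const)) {
    warning("constant column(s) normalized to zeros: ",
            paste(colnames(m)[const], collapse = ", "))
    span[const] <- 1
  }
  out <- sweep(sweep(m, 2L, lo, `-`), 2L, span, `/`)
  out[, const] <- 0
  attr(out, "ranges") <- rbind(min = lo, max = hi)
  out
}

#' Pearson correlation matrix of a feature matrix
#'
#' @param m numeric matrix, >= 2 rows; constant columns are an error because
#'   Pearson r is undefined for them.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 rows")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate statistics: constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Greedy priority-ordered feature selection
#'
#' Visits attributes in priority order; keeps an attribute iff its absolute
#' correlation with every already-kept attribute is at or below `threshold`.
#' Screening uses |r|: a strong negative correlation is as redundant as a
#' strong positive one.
#'
#' @param correlation symmetric attribute correlation matrix (named dims).
#' @param threshold |r| cutoff, default 0.7.
#' @param priority character vector: a total order over the attributes,
#'   most important first. Default: column order of `correlation`.
#' @return a `selection_report` with `correlation`, `threshold`, `priority`,
#'   `kept`, `removed`.
#' @export
select_features <- function(correlation, threshold = 0.7, priority = NULL) {
  attrs <- colnames(correlation)
  if (is.null(attrs)) stop("correlation matrix must have named columns")
  if (is.null(priority)) priority <- attrs
  missing <- setdiff(attrs, priority)
  if (length(missing))
    stop("configuration error: attribute(s) missing from priority: ",
         paste(missing, collapse = ", "))
  priority <- priority[priority %in% attrs]
  kept <- character(0); removed <- character(0)
  for (a in priority) {
    if (length(kept) && any(abs(correlation[a, kept]) > threshold))
      removed <- c(removed, a)
    else kept <- c(kept, a)
  }
  structure(list(correlation = correlation, threshold = threshold,
                 priority = priority, kept = kept, removed = removed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> threshold |r| <= %g; kept: %s; removed: %s\n",
              x$threshold, paste(x$kept, collapse = ", "),
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Assemble the clustering feature matrix for a scenario
#'
#' Rows are the in-mask cells of the stack in canonical (column-major)
#' order. Columns are the kept attributes (after [select_features] iff the
#' scenario decreases features), plus the cell-center x/y iff the scenario
#' includes coordinates. Range normalization is applied last, so coordinate
#' columns are normalized like any other column.
#'
#' @param stack an `attribute_stack`.
#' @param scenario a `scenario_spec` (or scenario name string).
#' @param priority feature-selection priority order; default stack layer order.
#' @param threshold |r| cutoff for selection.
#' @return the feature matrix with attributes `"selection"` (a
#'   `selection_report` or `NULL`) and `"cells"` (in-mask cell indices).
#' @export
build_feature_matrix <- function(stack, scenario, priority = NULL,
                                 threshold = 0.7) {
  if (is.character(scenario)) scenario <- parse_scenario(scenario)
  cells <- mask_cells(stack)
  if (!length(cells)) stop("empty mask: no cells to cluster")
  m <- vapply(stack$layers, function(v) v[cells], numeric(length(cells)))
  if (!is.matrix(m)) m <- matrix(m, nrow = length(cells),
                                 dimnames = list(NULL, names(stack$layers)))
  if (anyNA(m)) stop("missing values inside the field mask")
  sel <- NULL
  if (scenario$feature_decrease) {
    sel <- select_features(correlation_matrix(m), threshold = threshold,
                           priority = priority)
    m <- m[, sel$kept, drop = FALSE]
  }
  if (scenario$include_coords) {
    ctr <- cell_centers(stack, cells)
    m <- cbind(m, x = ctr[, "x"], y = ctr[, "y"])
  }
  if (scenario$normalize) m <- range_normalize(m)
  attr(m, "selection") <- sel
  attr(m, "cells") <- cells
  attr(m, "scenario") <- scenario$name
  m
}
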