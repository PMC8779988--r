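# Core spatial data types: point sample sets, single-layer grids, attribute
# stacks and label rasters. All coordinates are projected meters; geometry is
# anchored at the lower-left corner of the lower-left cell, row 1 of a value
# matrix is the northernmost row (ESRI ASCII convention).

#' Create a grid geometry descriptor
#'
#' Describes a regular raster grid: origin at the lower-left corner of the
#' lower-left cell, square cells of `cell_size` meters, `nrows` rows counted
#' from north and `ncols` columns counted from west.
#'
#' @param origin numeric length-2, `(x0, y0)` of the lower-left cell corner
#'   in meters.
#' @param cell_size cell edge length in meters, `> 0`.
#' @param ncols,nrows grid dimensions.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(origin, cell_size, ncols, nrows) {
  origin <- as.numeric(origin)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite numbers (x0, y0)")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be > 0")
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (ncols < 1L || nrows < 1L) stop("grid must have at least one cell")
  structure(list(origin = origin, cell_size = as.numeric(cell_size),
                 ncols = ncols, nrows = nrows),
            class = "grid_geometry")
}

geometry_of <- function(x) {
  grid_geometry(x$origin, x$cell_size, x$ncols, x$nrows)
}

same_geometry <- function(a, b, tol = 1e-9) {
  a <- geometry_of(a); b <- geometry_of(b)
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$cell_size - b$cell_size) <= tol * max(1, a$cell_size) &&
    all(abs(a$origin - b$origin) <= tol * max(1, a$cell_size))
}

#' Cell-center coordinates of a grid
#'
#' @param geom a `grid_geometry` (or any object carrying one).
#' @param cells optional integer vector of cell indices in R's column-major
#'   matrix order (the canonical in-mask cell order used throughout the
#'   package); default all cells.
#' @return a two-column matrix `x`, `y` of cell centers in meters.
#' @export
cell_centers <- function(geom, cells = NULL) {
  geom <- geometry_of(geom)
  if (is.null(cells)) cells <- seq_len(geom$nrows * geom$ncols)
  row <- ((cells - 1L) %% geom$nrows) + 1L      # 1 = northernmost
  col <- ((cells - 1L) %/% geom$nrows) + 1L     # 1 = westernmost
  cbind(x = geom$origin[1] + (col - 0.5) * geom$cell_size,
        y = geom$origin[2] + (geom$nrows - row + 0.5) * geom$cell_size)
}

#' Create a single-layer grid
#'
#' @param values numeric matrix, rows from north; `NA` marks no-data.
#' @inheritParams grid_geometry
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, origin = c(0, 0), cell_size = 5) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  geom <- grid_geometry(origin, cell_size, ncol(values), nrow(values))
  structure(list(values = values, origin = geom$origin,
                 cell_size = geom$cell_size,
                 ncols = geom$ncols, nrows = geom$nrows),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer> %d x %d cells of %g m, origin (%g, %g), %d no-data\n",
              x$nrows, x$ncols, x$cell_size, x$origin[1], x$origin[2],
              sum(is.na(x$values))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Point sample sets

#' Create a point sample set
#'
#' Irregular geo-referenced multi-attribute observations, e.g. online
#' vis-NIR soil scanner readings.
#'
#' @param x,y projected coordinates in meters.
#' @param attributes data frame with one numeric column per attribute.
#' @return an object of class `point_samples` with fields `x`, `y`,
#'   `attributes`, `n`.
#' @export
point_samples <- function(x, y, attributes) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("at least one point is required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  attributes <- as.data.frame(attributes, optional = TRUE)
  if (nrow(attributes) != length(x))
    stop("attribute columns must have one row per point")
  if (ncol(attributes) < 1L) stop("no attribute columns")
  if (anyDuplicated(names(attributes)))
    stop("attribute names must be unique")
  bad <- names(attributes)[!vapply(attributes, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric attribute column(s): ", paste(bad, collapse = ", "))
  structure(list(x = x, y = y, attributes = attributes, n = length(x)),
            class = "point_samples")
}

#' @export
print.point_samples <- function(x, ...) {
  cat(sprintf("<point_samples> n = %d, attributes: %s\n", x$n,
              paste(names(x$attributes), collapse = ", ")))
  invisible(x)
}

#' Read a delimited point table
#'
#' Reads a CSV with a header row; the two named coordinate columns become
#' `x`/`y` and every remaining numeric column becomes an attribute.
#' Row order is preserved.
#'
#' @param path file path.
#' @param x_col,y_col names of the coordinate columns.
#' @param sep field separator.
#' @return a [point_samples] object.
#' @export
read_point_table <- function(path, x_col = "x", y_col = "y", sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (cc in c(x_col, y_col))
    if (!cc %in% names(raw))
      stop("format error: coordinate column '", cc, "' not found in ", path)
  attrs <- raw[setdiff(names(raw), c(x_col, y_col))]
  if (ncol(attrs) < 1L) stop("no attribute columns in ", path)
  for (nm in names(attrs)) {
    col <- attrs[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                     col[bad[1]], bad[1], nm))
      attrs[[nm]] <- num
    }
  }
  for (cc in c(x_col, y_col))
    if (!is.numeric(raw[[cc]]))
      stop("parse error: coordinate column '", cc, "' is not numeric")
  point_samples(raw[[x_col]], raw[[y_col]], attrs)
}

#' Write a point sample set as CSV
#'
#' @param points a [point_samples] object.
#' @param path output file path.
#' @export
write_point_table <- function(points, path) {
  df <- data.frame(x = points$x, y = points$y, check.names = FALSE)
  df <- cbind(df, points$attributes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grids

#' Read an ESRI ASCII grid
#'
#' Standard `.asc` header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`), then `nrows` lines of `ncols`
#' values, first line = northernmost row. NODATA cells become `NA`.
#'
#' @param path file path.
#' @return a [grid_layer].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list(); i <- 1L
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2]); i <- i + 1L
    } else break
    if (i > length(lines)) break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("format error: missing header keyword(s): ", paste(miss, collapse = ", "))
  if (is.na(hdr$cellsize) || hdr$cellsize <= 0)
    stop("validation error: cellsize must be > 0")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop(sprintf("format error: expected %d values, found %d", nc * nr, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_layer(m, origin = c(hdr$xllcorner, hdr$yllcorner), cell_size = hdr$cellsize)
}

#' Write a grid layer as ESRI ASCII
#'
#' @param layer a [grid_layer] (or a label raster).
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @param digits significant digits to print.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999, digits = 15) {
  m <- layer$values
  hdr <- c(sprintf("ncols %d", layer$ncols),
           sprintf("nrows %d", layer$nrows),
           sprintf("xllcorner %.10g", layer$origin[1]),
           sprintf("yllcorner %.10g", layer$origin[2]),
           sprintf("cellsize %.10g", layer$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) {
    r[is.na(r)] <- nodata
    paste(formatC(r, format = "g", digits = digits), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Attribute stacks and label rasters

#' Stack co-registered single-layer grids
#'
#' @param layers a named list of [grid_layer]s on identical geometry.
#' @return an `attribute_stack`: geometry, a logical `mask` matrix (the
#'   conjunction of per-layer data masks) and a named list of value matrices.
#' @export
stack_layers <- function(layers) {
  if (!length(layers)) stop("at least one layer is required")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  g <- geometry_of(layers[[1]])
  for (i in seq_along(layers))
    if (!same_geometry(layers[[i]], g))
      stop("alignment error: layer '", names(layers)[i],
           "' does not share the stack geometry")
  mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  structure(list(origin = g$origin, cell_size = g$cell_size,
                 ncols = g$ncols, nrows = g$nrows,
                 mask = mask,
                 layers = lapply(layers, function(l) l$values)),
            class = "attribute_stack")
}

#' @export
print.attribute_stack <- function(x, ...) {
  cat(sprintf("<attribute_stack> %d x %d cells of %g m, %d in mask, layers: %s\n",
              x$nrows, x$ncols, x$cell_size, sum(x$mask),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract one layer of a stack as a grid_layer
#' @param stack an `attribute_stack`.
#' @param name layer name.
#' @export
stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) stop("no layer '", name, "'")
  v <- stack$layers[[name]]
  v[!stack$mask] <- NA_real_
  grid_layer(v, stack$origin, stack$cell_size)
}

#' Indices of in-mask cells in canonical (column-major) order
#' @param stack an `attribute_stack` or `label_raster`.
#' @export
mask_cells <- function(stack) which(stack$mask)

#' Create a label raster
#'
#' @param labels integer matrix; `>= 0` cluster ids, `-1` outliers (density
#'   methods only), `NA` outside the field mask.
#' @inheritParams grid_geometry
#' @return an object of class `label_raster`.
#' @export
label_raster <- function(labels, origin = c(0, 0), cell_size = 5) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  ok <- labels[!is.na(labels)]
  if (length(ok) && any(ok < -1L))
    stop("labels must be >= 0, or -1 for outliers")
  g <- grid_geometry(origin, cell_size, ncol(labels), nrow(labels))
  structure(list(values = labels, mask = !is.na(labels),
                 origin = g$origin, cell_size = g$cell_size,
                 ncols = g$ncols, nrows = g$nrows),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  lv <- x$values[x$mask]
  cat(sprintf("<label_raster> %d x %d cells, %d in mask, labels {%s}, %d outliers\n",
              x$nrows, x$ncols, sum(x$mask),
              paste(sort(unique(lv[lv >= 0])), collapse = ","), sum(lv == -1L)))
  invisible(x)
}

#' Convert a label raster to/from a grid layer for ASCII-grid IO
#' @param labels a `label_raster`.
#' @export
labels_as_layer <- function(labels) {
  grid_layer(`storage.mode<-`(labels$values, "double"),
             labels$origin, labels$cell_size)
}

#' @rdname labels_as_layer
#' @param layer a [grid_layer] holding integer labels.
#' @export
layer_as_labels <- function(layer) {
  label_raster(round(layer$values), layer$origin, layer$cell_size)
}
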