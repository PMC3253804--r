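#' Geographic analysis grid
#'
#' A `grid_spec` defines a regular lon/lat grid of square cells in decimal
#' degrees. Cells are half-open: `[x0, x0 + cell_size) x [y0, y0 + cell_size)`,
#' so a point on a shared boundary belongs to the cell on its east/north side
#' and every point in the extent maps to exactly one cell. Cells are indexed
#' row-major from the south-west corner (cell 1 = lower-left).
#'
#' @param xll,yll lower-left corner of the grid (decimal degrees).
#' @param cell_size cell edge in decimal degrees (default 1/6 = 10 arcmin).
#' @param n_cols,n_rows grid dimensions.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(xll, yll, cell_size = 1 / 6, n_cols, n_rows) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (n_cols < 1 || n_rows < 1) stop("grid must have at least one cell")
  structure(list(xll = xll, yll = yll, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows, cell %.6g deg, origin (%.6g, %.6g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$xll, x$yll))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Build a grid covering an extent
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param cell_size cell edge in degrees; the study default is 10 arcminutes
#'   (1/6 degree).
#' @param origin_snap if `TRUE` (default) the origin is snapped down to the
#'   largest multiple of `cell_size` not exceeding the extent minimum, which
#'   makes cell boundaries independent of the data extent.
#' @return a [grid_spec].
#' @export
make_grid <- function(extent, cell_size = 1 / 6, origin_snap = TRUE) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans")
  xll <- extent[1]; yll <- extent[3]
  if (origin_snap) {
    xll <- floor(round(extent[1] / cell_size, 9)) * cell_size
    yll <- floor(round(extent[3] / cell_size, 9)) * cell_size
  }
  n_cols <- ceiling(round((extent[2] - xll) / cell_size, 9))
  n_rows <- ceiling(round((extent[4] - yll) / cell_size, 9))
  grid_spec(xll, yll, cell_size, n_cols, n_rows)
}

#' Map points to grid cells
#'
#' Applies the half-open cell rule: a point exactly on a cell boundary is
#' assigned to the cell on its east/north side. Points outside the grid get
#' `NA`.
#'
#' @param grid a [grid_spec].
#' @param lon,lat point coordinates (vectors).
#' @return integer cell ids (row-major from the south-west corner).
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor(round((lon - grid$xll) / grid$cell_size, 9)) + 1L
  row <- floor(round((lat - grid$yll) / grid$cell_size, 9)) + 1L
  ok <- col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  out <- rep(NA_integer_, length(col))
  out[ok] <- (row[ok] - 1L) * grid$n_cols + col[ok]
  out
}

cell_col <- function(grid, cell) (cell - 1L) %% grid$n_cols + 1L
cell_row <- function(grid, cell) (cell - 1L) %/% grid$n_cols + 1L

#' Cell centers
#' @param grid a [grid_spec].
#' @param cell integer cell ids.
#' @return two-column matrix of center lon/lat.
#' @export
cell_center <- function(grid, cell) {
  cbind(lon = grid$xll + (cell_col(grid, cell) - 0.5) * grid$cell_size,
        lat = grid$yll + (cell_row(grid, cell) - 0.5) * grid$cell_size)
}

#' Raster of per-cell values
#'
#' Thin carrier for any statistic mapped onto a [grid_spec]: one numeric
#' value per cell, `NA` meaning nodata.
#'
#' @param grid a [grid_spec].
#' @param values numeric vector of length `n_cols * n_rows` in cell-id order
#'   (row-major from the south-west corner); defaults to all-`NA`.
#' @return an object of class `divmap_raster`.
#' @export
divmap_raster <- function(grid, values = rep(NA_real_, n_cells(grid))) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.numeric(values)
  if (length(values) != n_cells(grid))
    stop("values length must equal n_cols * n_rows")
  structure(list(grid = grid, values = values), class = "divmap_raster")
}

#' @export
print.divmap_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("divmap_raster on %d x %d grid: %d valued cells",
              x$grid$n_cols, x$grid$n_rows, length(v)))
  if (length(v) > 0)
    cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Write / read ESRI ASCII grids
#'
#' Serializes a [divmap_raster] as an ESRI ASCII grid (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows written north to south. Values survive a
#' round trip to at least 6 significant digits.
#'
#' @param raster a [divmap_raster].
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "divmap_raster"))
  g <- raster$grid
  if (!is.na(nodata) && any(raster$values == nodata, na.rm = TRUE))
    stop("a raster value collides with the NODATA sentinel ", nodata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$n_cols),
               paste("nrows", g$n_rows),
               paste("xllcorner", format(g$xll, digits = 12)),
               paste("yllcorner", format(g$yll, digits = 12)),
               paste("cellsize", format(g$cell_size, digits = 12)),
               paste("NODATA_value", nodata)), con)
  m <- matrix(raster$values, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  for (r in g$n_rows:1) {   # internal row 1 is the southern row
    v <- m[r, ]
    v_chr <- ifelse(is.na(v), as.character(nodata), format(v, digits = 9))
    writeLines(paste(v_chr, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_raster
#' @export
read_ascii_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 &&
        tolower(parts[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 hdr$ncols, hdr$nrows)
  if (length(vals) != n_cells(g))
    stop("value count does not match ncols x nrows in ", path)
  m <- matrix(vals, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m <- m[g$n_rows:1, , drop = FALSE]      # back to south-first internal order
  v <- as.vector(t(m))
  v[v == nodata] <- NA_real_
  divmap_raster(g, v)
}

#' Export grid cells as GeoJSON polygons
#'
#' Writes one GeoJSON `Feature` per requested cell, each a square polygon in
#' lon/lat with optional per-cell properties (e.g. the statistics table).
#'
#' @param grid a [grid_spec].
#' @param cell_ids integer cell ids to export.
#' @param properties optional data.frame, one row per cell id.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
cells_to_geojson <- function(grid, cell_ids, properties = NULL, path) {
  d <- grid$cell_size
  x0 <- grid$xll + (cell_col(grid, cell_ids) - 1) * d
  y0 <- grid$yll + (cell_row(grid, cell_ids) - 1) * d
  feats <- lapply(seq_along(cell_ids), function(i) {
    ring <- list(c(x0[i], y0[i]), c(x0[i] + d, y0[i]),
                 c(x0[i] + d, y0[i] + d), c(x0[i], y0[i] + d),
                 c(x0[i], y0[i]))
    props <- list(cell_id = cell_ids[i])
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a per-cell statistics table
#'
#' One CSV row per cell with the cell id, its center coordinates, the
#' re-sampled tree count and every statistic; statistics suppressed below the
#' minimum sample size are written as empty fields. Optionally also exports
#' the occupied cells as GeoJSON polygons carrying the same attributes.
#'
#' @param stats a `cell_stats` data.frame from [compute_cell_stats()].
#' @param path output CSV path.
#' @param geojson optional path for a GeoJSON polygon export of the cells.
#' @return `path`, invisibly.
#' @export
write_cell_stats <- function(stats, path, geojson = NULL) {
  utils::write.csv(stats, path, row.names = FALSE, na = "")
  if (!is.null(geojson)) {
    grid <- attr(stats, "grid")
    if (is.null(grid)) stop("stats table carries no grid attribute")
    cells_to_geojson(grid, stats$cell_id,
                     stats[setdiff(names(stats), "cell_id")], geojson)
  }
  invisible(path)
}

#' Rasterize a statistics column
#'
#' @param stats a `cell_stats` data.frame from [compute_cell_stats()].
#' @param column name of the statistic column to map.
#' @return a [divmap_raster] with the statistic in occupied cells.
#' @export
stats_raster <- function(stats, column) {
  grid <- attr(stats, "grid")
  if (is.null(grid)) stop("stats table carries no grid attribute")
  if (!column %in% names(stats)) stop("no such statistic: ", column)
  r <- divmap_raster(grid)
  r$values[stats$cell_id] <- stats[[column]]
  r
}
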