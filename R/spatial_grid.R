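#' Circular-neighborhood stencil
#'
#' Builds the set of cell offsets making up a circular neighborhood of the
#' given diameter on a grid of square cells. The anchor is a grid node (a
#' cell corner); a cell belongs to the neighborhood when its center lies
#' strictly within `diameter / 2` of the anchor node. For the study defaults
#' (10-arcminute cells, one-degree diameter) this is the 6 x 6 block of cells
#' around the node minus its four corners: exactly 32 cells.
#'
#' Offsets are expressed as (column, row) displacements of each member cell
#' relative to the cell whose lower-left corner is the anchor node.
#'
#' @param cell_size cell edge in degrees (default 1/6).
#' @param diameter neighborhood diameter in degrees (default 1).
#' @return integer matrix with columns `dc`, `dr`, one row per member cell,
#'   of class `neighborhood_mask`.
#' @export
neighborhood_mask <- function(cell_size = 1 / 6, diameter = 1) {
  if (diameter < cell_size) stop("diameter must be at least cell_size")
  r2 <- (diameter / (2 * cell_size))^2   # radius in cell units, squared
  span <- ceiling(diameter / (2 * cell_size))
  off <- seq.int(-span, span - 1L)
  grid <- expand.grid(dc = off, dr = off)
  cen2 <- (grid$dc + 0.5)^2 + (grid$dr + 0.5)^2
  keep <- cen2 < r2 - 1e-12     # strict center-in-circle rule
  if (!any(keep))
    warning("degenerate neighborhood: no cell center falls strictly within ",
            "the radius")
  m <- as.matrix(grid[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  structure(m, class = c("neighborhood_mask", "matrix", "array"),
            cell_size = cell_size, diameter = diameter)
}

#' @export
print.neighborhood_mask <- function(x, ...) {
  cat(sprintf("neighborhood_mask: %d cells (cell %.6g deg, diameter %.6g deg)\n",
              nrow(x), attr(x, "cell_size"), attr(x, "diameter")))
  invisible(x)
}

#' Re-sample trees into surrounding grid cells
#'
#' Copies each georeferenced individual into every grid cell of its circular
#' neighborhood, so that each cell's statistics later summarize the trees of
#' the surrounding landscape rather than only those inside the cell. Under
#' the default node-anchored rule each tree is snapped to its nearest grid
#' node and the fixed stencil from [neighborhood_mask()] is applied, giving
#' every tree exactly `nrow(mask)` cells (32 for the study defaults). The
#' grid is extended -- never clipped -- so border trees contribute the full
#' stencil.
#'
#' An alternative tree-centered rule (`anchor = "tree"`) takes the cells
#' whose centers lie strictly within `diameter / 2` of the tree itself; its
#' cell count varies with the tree's position within its cell (29-32 for the
#' defaults).
#'
#' @param table a [genotype_table].
#' @param grid a [grid_spec]; extended as needed.
#' @param mask a [neighborhood_mask] (its `cell_size` must match `grid`).
#' @param anchor `"node"` (default, fixed stencil) or `"tree"`.
#' @return a `cell_assignment`: list with the (possibly extended) `grid`, an
#'   integer vector `cell` and parallel vector `sample` (row index into
#'   `table`), one entry per (tree, cell) record, plus the `mask`.
#' @export
resample_trees <- function(table, grid, mask, anchor = c("node", "tree")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(table, "genotype_table"), inherits(grid, "grid_spec"))
  if (abs(attr(mask, "cell_size") - grid$cell_size) > 1e-9)
    stop("mask cell_size does not match grid cell_size")
  d <- grid$cell_size
  lon <- table$samples$lon; lat <- table$samples$lat
  if (anyNA(lon) || anyNA(lat)) stop("all samples must have coordinates")
  n <- length(lon); m <- nrow(mask)

  if (anchor == "node") {
    # half-up tie-break (not round-half-even) keeps snapping translation-
    # invariant for trees exactly midway between nodes
    node_i <- as.integer(floor(round((lon - grid$xll) / d + 0.5, 9)))
    node_j <- as.integer(floor(round((lat - grid$yll) / d + 0.5, 9)))
    # cell with offset (dc, dr) has column node_i + dc + 1 (1-based)
    cols <- rep(node_i, each = m) + rep(mask[, "dc"], times = n) + 1L
    rows <- rep(node_j, each = m) + rep(mask[, "dr"], times = n) + 1L
    samp <- rep(seq_len(n), each = m)
  } else {
    radius <- attr(mask, "diameter") / 2
    span <- ceiling(radius / d) + 1L
    base_c <- floor(round((lon - grid$xll) / d, 9))
    base_r <- floor(round((lat - grid$yll) / d, 9))
    off <- seq.int(-span, span)
    block <- expand.grid(dc = off, dr = off)
    b <- nrow(block)
    cols <- rep(base_c, each = b) + rep(block$dc, times = n) + 1L
    rows <- rep(base_r, each = b) + rep(block$dr, times = n) + 1L
    samp <- rep(seq_len(n), each = b)
    cx <- grid$xll + (cols - 0.5) * d
    cy <- grid$yll + (rows - 0.5) * d
    keep <- (cx - lon[samp])^2 + (cy - lat[samp])^2 < radius^2 - 1e-12
    cols <- cols[keep]; rows <- rows[keep]; samp <- samp[keep]
  }

  # extend the grid so every record has a legal cell
  min_c <- min(cols, 1L); max_c <- max(cols, grid$n_cols)
  min_r <- min(rows, 1L); max_r <- max(rows, grid$n_rows)
  if (min_c < 1L || min_r < 1L || max_c > grid$n_cols || max_r > grid$n_rows) {
    pad_w <- 1L - min_c; pad_s <- 1L - min_r
    grid <- grid_spec(grid$xll - max(pad_w, 0L) * d,
                      grid$yll - max(pad_s, 0L) * d, d,
                      max_c - min_c + 1L, max_r - min_r + 1L)
    cols <- cols + max(pad_w, 0L)
    rows <- rows + max(pad_s, 0L)
  }
  cell <- (rows - 1L) * grid$n_cols + cols
  structure(list(grid = grid, cell = cell, sample = samp,
                 sample_id = table$samples$sample_id, mask = mask),
            class = "cell_assignment")
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf("cell_assignment: %d records (%d trees x neighborhood), %d occupied cells\n",
              length(x$cell), length(unique(x$sample)),
              length(unique(x$cell))))
  invisible(x)
}

#' Re-sampled tree counts per cell
#'
#' @param assignment a `cell_assignment` from [resample_trees()].
#' @return a [divmap_raster] of per-cell record counts; cells with no
#'   re-sampled tree are nodata.
#' @export
cell_counts <- function(assignment) {
  stopifnot(inherits(assignment, "cell_assignment"))
  g <- assignment$grid
  counts <- tabulate(assignment$cell, nbins = n_cells(g))
  v <- as.numeric(counts)
  v[v == 0] <- NA_real_
  divmap_raster(g, v)
}
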