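#' Reverse-jackknife outlier detection
#'
#' Flags values separated from the body of the sorted distribution, at
#' either extreme, by a gap exceeding the critical threshold
#' `t = (0.95 * sqrt(n) + 0.2) * (range / 50)`. Working outward from each
#' tail of the sorted unique values, a tail is cut where its adjacent gap
#' both exceeds `t` and strictly dominates every gap remaining in the body
#' (so evenly spaced data are never flagged); all values beyond the cut, and
#' their duplicates, are outliers. The procedure is deterministic and
#' invariant under affine rescaling, since both the gaps and the threshold
#' scale with the range.
#'
#' @param values numeric vector (n >= 3 finite values required; fewer, or a
#'   zero range, yields no outliers with a warning).
#' @return integer indices into `values` of the flagged outliers.
#' @export
reverse_jackknife <- function(values) {
  finite <- is.finite(values)
  v <- values[finite]
  n <- length(v)
  if (n < 3) {
    warning("reverse_jackknife needs at least 3 finite values")
    return(integer(0))
  }
  rng <- diff(range(v))
  if (rng == 0) return(integer(0))
  thr <- (0.95 * sqrt(n) + 0.2) * (rng / 50)
  u <- sort(unique(v))
  m <- length(u)
  if (m < 3) return(integer(0))
  gaps <- diff(u)
  lo <- 1L; hi <- m
  repeat {
    if (hi - lo < 2L) break
    body_gaps <- gaps[lo:(hi - 1L)]
    g_lo <- body_gaps[1]
    g_hi <- body_gaps[length(body_gaps)]
    interior <- body_gaps[-c(1L, length(body_gaps))]
    cut <- FALSE
    if (g_hi >= g_lo) {
      if (g_hi > thr && all(g_hi > c(interior, g_lo))) { hi <- hi - 1L; cut <- TRUE }
    } else {
      if (g_lo > thr && all(g_lo > c(interior, g_hi))) { lo <- lo + 1L; cut <- TRUE }
    }
    if (!cut) break
  }
  out_vals <- c(if (lo > 1L) u[1:(lo - 1L)], if (hi < m) u[(hi + 1L):m])
  which(values %in% out_vals)
}

#' Coordinate screening against climate layers
#'
#' Flags probable georeferencing errors: a sample whose location is a
#' [reverse_jackknife()] outlier on at least `min_vars` of the environmental
#' layers (classically the 19 bioclim variables) is marked as a climate
#' outlier. Samples falling outside the layer extent are flagged as
#' unresolvable, not dropped.
#'
#' @param table a [genotype_table].
#' @param env an `env_stack` (see [simulate_env_stack()]) or list of
#'   [divmap_raster]s on a shared grid.
#' @param min_vars number of offending variables required (default 2).
#' @return a `cleaning_report` data.frame: `sample_id`, `n_outlier_vars`,
#'   logical `climate_outlier`, `outside_extent`, `excluded`, plus one
#'   logical column per layer.
#' @export
flag_climate_outliers <- function(table, env, min_vars = 2) {
  vals <- extract_env(env, table$samples$lon, table$samples$lat)
  n_layers <- ncol(vals)
  if (n_layers < 19)
    warning("only ", n_layers, " environmental layers supplied (19 expected); ",
            "proceeding")
  n <- n_samples(table)
  marks <- matrix(FALSE, n, n_layers,
                  dimnames = list(NULL, colnames(vals)))
  for (j in seq_len(n_layers)) {
    idx <- reverse_jackknife(vals[, j])
    marks[idx, j] <- TRUE
  }
  n_out <- rowSums(marks)
  outside <- rowSums(is.na(vals)) == n_layers
  rep <- data.frame(sample_id = table$samples$sample_id,
                    n_outlier_vars = n_out,
                    climate_outlier = n_out >= min_vars,
                    outside_extent = outside,
                    stringsAsFactors = FALSE)
  rep$excluded <- rep$climate_outlier
  out <- cbind(rep, as.data.frame(marks))
  class(out) <- c("cleaning_report", "data.frame")
  out
}

# squared euclidean distance from points to a polygon ring (degree space)
dist_to_ring <- function(px, py, ring) {
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  vapply(seq_along(px), function(i) {
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 == 0, 0,
                pmin(1, pmax(0, ((px[i] - x1) * dx + (py[i] - y1) * dy) / len2)))
    min((px[i] - (x1 + t * dx))^2 + (py[i] - (y1 + t * dy))^2)
  }, numeric(1))
}

#' Administrative-unit consistency check
#'
#' Flags samples whose coordinates lie farther than `buffer` degrees from
#' the polygon of their declared first-level administrative unit. Distances
#' are planar in degree space, matching the buffer's definition (20
#' arcminutes = 1/3 degree). Samples declaring a unit with no supplied
#' polygon are marked unresolvable but not excluded.
#'
#' @param table a [genotype_table] whose samples carry an `admin1` column.
#' @param polygons named list of polygon rings (two-column lon/lat
#'   matrices), names matching `admin1` values.
#' @param buffer tolerated distance outside the polygon, decimal degrees
#'   (default 1/3).
#' @return a `cleaning_report` data.frame with `admin_mismatch`,
#'   `admin_unresolved` and `excluded` columns.
#' @export
flag_admin_mismatch <- function(table, polygons, buffer = 1 / 3) {
  if (!"admin1" %in% names(table$samples))
    stop("table has no admin1 column")
  s <- table$samples
  n <- nrow(s)
  mismatch <- unresolved <- logical(n)
  for (i in seq_len(n)) {
    poly <- polygons[[s$admin1[i]]]
    if (is.null(poly)) { unresolved[i] <- TRUE; next }
    inside <- mgcv::in.out(rbind(poly, poly[1, ]),
                           cbind(s$lon[i], s$lat[i]))
    if (!inside) {
      d <- sqrt(dist_to_ring(s$lon[i], s$lat[i], poly))
      mismatch[i] <- d > buffer
    }
  }
  out <- data.frame(sample_id = s$sample_id,
                    admin_mismatch = mismatch,
                    admin_unresolved = unresolved,
                    excluded = mismatch,
                    stringsAsFactors = FALSE)
  class(out) <- c("cleaning_report", "data.frame")
  out
}

#' Remove samples excluded by cleaning reports
#'
#' @param table a [genotype_table].
#' @param ... one or more `cleaning_report` data.frames (climate and/or
#'   administrative); a sample is removed when any report excludes it.
#' @return the table minus excluded samples; the number removed is reported
#'   via `message()`.
#' @export
clean_dataset <- function(table, ...) {
  reports <- list(...)
  if (length(reports) == 0) return(table)
  excl <- rep(FALSE, n_samples(table))
  for (rep in reports) {
    stopifnot(inherits(rep, "cleaning_report"))
    i <- match(rep$sample_id, table$samples$sample_id)
    if (anyNA(i)) stop("cleaning report names unknown samples")
    excl[i] <- excl[i] | rep$excluded
  }
  message("clean_dataset: removing ", sum(excl), " of ", length(excl),
          " samples")
  if (all(excl)) warning("all samples excluded")
  table[!excl]
}
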