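#' Configuration for a synthetic genotype landscape
#'
#' Describes a georeferenced microsatellite landscape with known truth, at
#' the scale of the Andean study system the package targets: roughly 1,500
#' trees sampled in clusters over a wide extent, nine loci with about eight
#' alleles each, two ancestral gene pools meeting along a latitudinal cline,
#' a region of elevated inbreeding, a high-diversity hotspot carrying extra
#' low-frequency alleles, a clonally propagated cultivar patch, and a
#' genebank (ex situ) subset from which the hotspot's extra alleles are
#' withheld.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param n_trees number of individuals.
#' @param n_loci number of loci.
#' @param n_alleles integer vector (recycled to `n_loci`) of ancestral
#'   allele counts per locus.
#' @param n_hubs,hub_sd sampling is clustered around `n_hubs` random hubs
#'   with Gaussian scatter `hub_sd` (degrees), emulating village-based
#'   collecting rather than uniform coverage.
#' @param ancestral `"graded"` (two correlated-but-distinct frequency
#'   sets), `"disjoint"` (non-overlapping allele supports, maximal
#'   cluster signal) or `"identical"` (a single gene pool).
#' @param cline_mid,cline_scale latitude midpoint and logistic scale of the
#'   admixture cline; membership in cluster A is
#'   `1 / (1 + exp(-(lat - cline_mid) / cline_scale))`.
#' @param base_f baseline inbreeding coefficient.
#' @param inbreeding_region `list(center = c(lon, lat), radius, f)` or
#'   `NULL`; trees within `radius` degrees of `center` are simulated with
#'   inbreeding coefficient `f`.
#' @param hotspot `list(center, radius, n_extra, extra_freq)` or `NULL`;
#'   trees inside draw each locus from a mixture that adds `n_extra` extra
#'   alleles at frequency `extra_freq` each.
#' @param clonal_patch `list(center, radius, fraction)` or `NULL`; inside
#'   the patch, a `fraction` of trees are exact copies of the reference
#'   cultivar genotype.
#' @param reference_genotype loci x 2 matrix, or `NULL` for the default
#'   cultivar (heterozygous at all loci but the last -- 8 of 9 under the
#'   defaults).
#' @param exsitu_fraction fraction of trees labeled ex situ.
#' @param withhold_hotspot if `TRUE`, ex situ trees are drawn only from
#'   non-carriers of the hotspot's extra alleles, planting an exact,
#'   regionally confined genebank gap.
#' @param missing_rate per-genotype missing probability.
#' @param seed integer seed; the whole landscape is reproducible from it.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent = c(-81, -63, -19, 1),
                             n_trees = 1504,
                             n_loci = 9,
                             n_alleles = c(rep(8, 8), 7),
                             n_hubs = 14, hub_sd = 0.4,
                             ancestral = c("graded", "disjoint", "identical"),
                             cline_mid = -9, cline_scale = 1.5,
                             base_f = 0,
                             inbreeding_region = list(center = c(-65.5, -17.5),
                                                      radius = 2.5, f = 0.3),
                             hotspot = list(center = c(-78.5, -7),
                                            radius = 1.2, n_extra = 2,
                                            extra_freq = 0.04),
                             clonal_patch = list(center = c(-77, -12),
                                                 radius = 0.7,
                                                 fraction = 0.9),
                             reference_genotype = NULL,
                             exsitu_fraction = 502 / 1504,
                             withhold_hotspot = TRUE,
                             missing_rate = 0,
                             seed = 42) {
  ancestral <- match.arg(ancestral)
  n_alleles <- rep_len(n_alleles, n_loci)
  stopifnot(base_f >= 0, base_f < 1, missing_rate >= 0, missing_rate <= 1,
            exsitu_fraction >= 0, exsitu_fraction <= 1)
  if (withhold_hotspot &&
      (is.null(hotspot) || hotspot$n_extra < 1 || hotspot$extra_freq <= 0))
    stop("withhold_hotspot requires a hotspot with extra alleles of ",
         "positive frequency")
  structure(list(extent = extent, n_trees = n_trees, n_loci = n_loci,
                 n_alleles = n_alleles, n_hubs = n_hubs, hub_sd = hub_sd,
                 ancestral = ancestral, cline_mid = cline_mid,
                 cline_scale = cline_scale, base_f = base_f,
                 inbreeding_region = inbreeding_region, hotspot = hotspot,
                 clonal_patch = clonal_patch,
                 reference_genotype = reference_genotype,
                 exsitu_fraction = exsitu_fraction,
                 withhold_hotspot = withhold_hotspot,
                 missing_rate = missing_rate, seed = seed),
            class = "landscape_config")
}

# allele labels mimic fragment sizes: ancestral alleles 100, 104, ... and
# hotspot extras 200, 204, ... (per locus; labels are opaque)
ancestral_labels <- function(n) 100L + 4L * seq_len(n) - 4L
extra_labels <- function(n) 200L + 4L * seq_len(n) - 4L

default_reference <- function(config) {
  m <- matrix(NA_integer_, config$n_loci, 2)
  for (l in seq_len(config$n_loci)) {
    lab <- ancestral_labels(config$n_alleles[l])
    m[l, ] <- if (l < config$n_loci) lab[1:2] else c(lab[1], lab[1])
  }
  m
}

in_circle <- function(lon, lat, region) {
  if (is.null(region)) return(rep(FALSE, length(lon)))
  (lon - region$center[1])^2 + (lat - region$center[2])^2 <= region$radius^2
}

#' Simulate a georeferenced genotype landscape with known truth
#'
#' Draws tree locations, ancestry, genotypes and conservation status from a
#' [landscape_config()]. Non-clonal genotypes follow the standard
#' inbreeding mixture at each locus: with mixture frequencies
#' `p = q * p_A + (1 - q) * p_B`, `P(homozygote ii) = p_i^2 + F *
#' p_i * (1 - p_i)` and `P(heterozygote ij) = 2 * p_i * p_j * (1 - F)`, so
#' the expected fixation index equals the planted `F`. Clones copy the
#' reference genotype exactly. Fully reproducible from `config$seed`.
#'
#' @param config a [landscape_config].
#' @return list with `table` (a [genotype_table]), `truth` (per-tree
#'   data.frame: `sample_id`, `q_true`, `f_true`, `is_clone`,
#'   `in_hotspot`, `in_inbreeding_region`, `status`), `withheld`
#'   (data.frame of (locus, allele) pairs withheld from ex situ trees),
#'   `reference` (the cultivar genotype matrix) and `config`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  ext <- config$extent
  n <- config$n_trees
  L <- config$n_loci

  # clustered tree locations around sampling hubs
  margin <- min(1, (ext[2] - ext[1]) / 10, (ext[4] - ext[3]) / 10)
  hx <- stats::runif(config$n_hubs, ext[1] + margin, ext[2] - margin)
  hy <- stats::runif(config$n_hubs, ext[3] + margin, ext[4] - margin)
  hub <- sample.int(config$n_hubs, n, replace = TRUE)
  lon <- pmin(pmax(hx[hub] + stats::rnorm(n, 0, config$hub_sd), ext[1]),
              ext[2] - 1e-9)
  lat <- pmin(pmax(hy[hub] + stats::rnorm(n, 0, config$hub_sd), ext[3]),
              ext[4] - 1e-9)

  # guarantee the special regions are populated (hubs may miss them)
  place_in <- function(region, frac) {
    if (is.null(region)) return()
    k <- max(20L, round(frac * n))
    idx <- sample.int(n, k)
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- region$radius * sqrt(stats::runif(k))
    lon[idx] <<- pmin(pmax(region$center[1] + rad * cos(ang), ext[1]),
                      ext[2] - 1e-9)
    lat[idx] <<- pmin(pmax(region$center[2] + rad * sin(ang), ext[3]),
                      ext[4] - 1e-9)
  }
  place_in(config$hotspot, 0.08)
  place_in(config$clonal_patch, 0.05)
  place_in(config$inbreeding_region, 0.10)

  # ancestry cline (cluster A in the north under the defaults)
  q <- if (config$ancestral == "identical") rep(1, n) else
    1 / (1 + exp(-(lat - config$cline_mid) / config$cline_scale))

  # ancestral allele frequencies per locus
  p_a <- p_b <- vector("list", L)
  for (l in seq_len(L)) {
    A <- config$n_alleles[l]
    if (config$ancestral == "disjoint") {
      ha <- ceiling(A / 2)
      p_a[[l]] <- c(rep(1 / ha, ha), rep(0, A - ha))
      p_b[[l]] <- c(rep(0, ha), rep(1 / (A - ha), A - ha))
    } else {
      g1 <- stats::rgamma(A, 2); g2 <- stats::rgamma(A, 2)
      p_a[[l]] <- g1 / sum(g1)
      p_b[[l]] <- if (config$ancestral == "identical") p_a[[l]] else
        g2 / sum(g2)
    }
  }

  in_hot <- in_circle(lon, lat, config$hotspot)
  in_inb <- in_circle(lon, lat, config$inbreeding_region)
  in_clo <- in_circle(lon, lat, config$clonal_patch)
  f_tree <- rep(config$base_f, n)
  if (!is.null(config$inbreeding_region))
    f_tree[in_inb] <- config$inbreeding_region$f

  is_clone <- rep(FALSE, n)
  if (!is.null(config$clonal_patch))
    is_clone[in_clo] <- stats::runif(sum(in_clo)) < config$clonal_patch$fraction

  reference <- if (is.null(config$reference_genotype))
    default_reference(config) else config$reference_genotype

  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    A <- config$n_alleles[l]
    labs <- ancestral_labels(A)
    pmat <- outer(q, p_a[[l]]) + outer(1 - q, p_b[[l]])   # n x A
    if (!is.null(config$hotspot) && config$hotspot$n_extra > 0) {
      ne <- config$hotspot$n_extra
      w <- ne * config$hotspot$extra_freq
      pmat <- cbind(pmat, matrix(0, n, ne))
      pmat[in_hot, ] <- cbind(pmat[in_hot, seq_len(A), drop = FALSE] * (1 - w),
                              matrix(config$hotspot$extra_freq,
                                     sum(in_hot), ne))
      labs <- c(labs, extra_labels(ne))
    }
    draw <- function() {
      u <- stats::runif(n)
      cum <- pmat %*% upper.tri(diag(ncol(pmat)), diag = TRUE)
      cum[, ncol(cum)] <- 1 + 1e-9      # guard against rounding in the tail
      max.col(u <= cum, ties.method = "first")
    }
    first <- draw()
    second <- draw()
    homo <- stats::runif(n) < f_tree          # inbreeding mixture law
    second[homo] <- first[homo]
    a1[, l] <- labs[first]
    a2[, l] <- labs[second]
  }

  for (l in seq_len(L)) {                      # clones copy the cultivar
    a1[is_clone, l] <- reference[l, 1]
    a2[is_clone, l] <- reference[l, 2]
  }

  # ex situ status: drawn from non-carriers of withheld alleles
  withheld <- data.frame(locus = character(0), allele = integer(0))
  carrier <- rep(FALSE, n)
  loci <- sprintf("SSR%02d", seq_len(L))
  if (config$withhold_hotspot) {
    ex_labs <- extra_labels(config$hotspot$n_extra)
    withheld <- data.frame(locus = rep(loci, each = length(ex_labs)),
                           allele = rep(ex_labs, times = L))
    carrier <- rowSums(matrix(a1 %in% ex_labs | a2 %in% ex_labs, n)) > 0
  }
  n_ex <- round(config$exsitu_fraction * n)
  pool <- which(!carrier)
  if (length(pool) < n_ex)
    stop("too few non-carrier trees to fill the ex situ quota")
  ex_idx <- sample(pool, n_ex)
  status <- rep("in_situ", n)
  status[ex_idx] <- "ex_situ"

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < config$missing_rate, n, L)
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }

  ids <- sprintf("T%04d", seq_len(n))
  table <- genotype_table(
    data.frame(sample_id = ids, lon = lon, lat = lat, status = status,
               stringsAsFactors = FALSE),
    loci, a1, a2)
  truth <- data.frame(sample_id = ids, q_true = q, f_true = f_tree,
                      is_clone = is_clone, in_hotspot = in_hot,
                      in_inbreeding_region = in_inb, status = status,
                      stringsAsFactors = FALSE)
  rownames(reference) <- loci
  list(table = table, truth = truth, withheld = withheld,
       reference = reference, config = config)
}

#' Simulate a smooth environmental raster stack
#'
#' Bioclim-style stand-in layers on an analysis grid: each layer is a
#' distinct linear gradient plus a smooth sinusoidal field and Gaussian
#' noise. Used for exercising the climate-outlier screen and the
#' distribution-surface evaluation; reproducible from `seed`.
#'
#' @param grid a [grid_spec].
#' @param n_layers number of layers (default 19).
#' @param seed integer seed.
#' @param noise_sd standard deviation of the per-cell noise.
#' @return an `env_stack`: list with the `grid`, a cells x layers `values`
#'   matrix and layer `names` (`bio01` ...).
#' @export
simulate_env_stack <- function(grid, n_layers = 19, seed = 42,
                               noise_sd = 0.05) {
  set.seed(seed)
  ctr <- cell_center(grid, seq_len(n_cells(grid)))
  lon <- ctr[, "lon"]; lat <- ctr[, "lat"]
  sx <- diff(range(lon)) + 1e-9; sy <- diff(range(lat)) + 1e-9
  vals <- matrix(NA_real_, n_cells(grid), n_layers)
  for (j in seq_len(n_layers)) {
    a <- stats::runif(1, -1, 1); b <- stats::runif(1, -1, 1)
    ph <- stats::runif(2, 0, 2 * pi)
    per <- stats::runif(1, 1, 3)
    vals[, j] <- a * (lon - min(lon)) / sx + b * (lat - min(lat)) / sy +
      0.3 * sin(2 * pi * per * (lon - min(lon)) / sx + ph[1]) *
        sin(2 * pi * per * (lat - min(lat)) / sy + ph[2]) +
      stats::rnorm(n_cells(grid), 0, noise_sd)
  }
  colnames(vals) <- sprintf("bio%02d", seq_len(n_layers))
  structure(list(grid = grid, values = vals,
                 names = colnames(vals)),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers on %d x %d grid\n",
              ncol(x$values), x$grid$n_cols, x$grid$n_rows))
  invisible(x)
}

#' Extract environmental values at point locations
#'
#' @param env an `env_stack` or a list of [divmap_raster]s sharing one
#'   grid.
#' @param lon,lat point coordinates.
#' @return points x layers numeric matrix; `NA` rows for points outside
#'   the grid.
#' @export
extract_env <- function(env, lon, lat) {
  if (inherits(env, "env_stack")) {
    cells <- cell_index(env$grid, lon, lat)
    out <- env$values[ifelse(is.na(cells), 1L, cells), , drop = FALSE]
    out[is.na(cells), ] <- NA_real_
    return(out)
  }
  stopifnot(is.list(env), length(env) > 0,
            all(vapply(env, inherits, logical(1), "divmap_raster")))
  g <- env[[1]]$grid
  for (r in env[-1])
    if (!isTRUE(all.equal(unclass(r$grid), unclass(g))))
      stop("environmental layers are on mismatched grids")
  cells <- cell_index(g, lon, lat)
  out <- vapply(env, function(r) r$values[ifelse(is.na(cells), 1L, cells)],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells))
  out[is.na(cells), ] <- NA_real_
  if (!is.null(names(env))) colnames(out) <- names(env)
  out
}

#' Write an environmental stack as ESRI ASCII grids
#'
#' @param env an `env_stack`.
#' @param dir output directory (created if absent); one `.asc` per layer.
#' @return the file paths, invisibly.
#' @export
write_env_stack <- function(env, dir) {
  stopifnot(inherits(env, "env_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(env$names, ".asc"))
  for (j in seq_along(paths))
    write_ascii_raster(divmap_raster(env$grid, env$values[, j]), paths[j])
  invisible(paths)
}
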