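#' Per-locus allele copy counts
#'
#' Tabulates, for a set of individuals, how many copies of each allele were
#' observed at each locus. The gene count N of a locus is twice its number
#' of non-missing genotypes; missing genotypes contribute nothing.
#'
#' @param table a [genotype_table].
#' @param rows sample indices to include (default all). Indices may repeat:
#'   the re-sampled trees of a cell, not the original ones, constitute its
#'   sample.
#' @return a named list, one element per locus: an integer vector of copy
#'   counts named by allele label.
#' @export
allele_counts <- function(table, rows = seq_len(n_samples(table))) {
  out <- lapply(seq_along(table$loci), function(l) {
    al <- c(table$a1[rows, l], table$a2[rows, l])
    al <- al[!is.na(al)]
    if (length(al) == 0) return(integer(0))
    tab <- table(al)
    cn <- as.integer(tab)
    names(cn) <- names(tab)
    cn
  })
  stats::setNames(out, table$loci)
}

#' Mean number of alleles per locus (Na)
#'
#' @param counts a per-locus allele count list from [allele_counts()], or a
#'   single locus's count vector.
#' @return arithmetic mean over loci of the number of distinct alleles
#'   observed; loci with no data are excluded with a warning.
#' @export
mean_alleles_per_locus <- function(counts) {
  if (!is.list(counts)) counts <- list(counts)
  n <- vapply(counts, sum, numeric(1))
  if (all(n == 0)) return(NA_real_)
  if (any(n == 0))
    warning(sum(n == 0), " locus/loci with no data excluded from Na")
  mean(vapply(counts[n > 0], length, integer(1)))
}

#' Rarefied allelic richness at a single locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, computed exactly from the hypergeometric distribution:
#' `E[A_g] = sum_i (1 - choose(N - N_i, g) / choose(N, g))`, where `N_i` is
#' the copy count of allele i and `N` the gene count. This removes the
#' sample-size bias of raw allele counts; the study standard is `g = 40`
#' genes (20 diploid trees).
#'
#' @param counts integer vector of allele copy counts at one locus.
#' @param g gene count to rarefy to (default 40).
#' @return expected allele count, or `NA` when fewer than `g` copies were
#'   observed.
#' @export
rarefied_richness <- function(counts, g = 40) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < g) return(NA_real_)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Expected heterozygosity (He)
#'
#' Gene diversity `1 - sum(p_i^2)` from the allele frequencies of a locus;
#' for a per-locus count list the mean over loci with data.
#'
#' @param counts a count vector for one locus, or a list from
#'   [allele_counts()].
#' @return He in `[0, 1]`; `NA` when no locus has data.
#' @export
expected_heterozygosity <- function(counts) {
  he1 <- function(cn) {
    N <- sum(cn)
    if (N == 0) return(NA_real_)
    1 - sum((cn / N)^2)
  }
  if (!is.list(counts)) return(he1(counts))
  v <- vapply(counts, he1, numeric(1))
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Observed heterozygosity (Ho)
#'
#' Fraction of non-missing genotypes carrying two different alleles, per
#' locus, averaged over loci.
#'
#' @param table a [genotype_table].
#' @param rows sample indices (default all; repeats allowed).
#' @return Ho in `[0, 1]`.
#' @export
observed_heterozygosity <- function(table, rows = seq_len(n_samples(table))) {
  het <- table$a1[rows, , drop = FALSE] != table$a2[rows, , drop = FALSE]
  v <- colMeans(het, na.rm = TRUE)   # NaN for loci with no data
  v <- v[!is.nan(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Fixation index (F)
#'
#' `F = 1 - Ho / He` per locus, averaged over polymorphic loci (He > 0);
#' monomorphic loci carry no information about inbreeding and are excluded.
#' Positive values indicate a heterozygote deficit (inbreeding), negative
#' values a heterozygote excess, as in clonally propagated heterozygous
#' cultivars.
#'
#' @param he,ho per-locus expected and observed heterozygosities (equal
#'   lengths; scalars allowed).
#' @return mean F over loci with He > 0, or `NA` if every locus has He = 0.
#' @export
fixation_index <- function(he, ho) {
  stopifnot(length(he) == length(ho))
  keep <- !is.na(he) & !is.na(ho) & he > 0
  if (!any(keep)) return(NA_real_)
  mean(1 - ho[keep] / he[keep])
}

# squared single-locus codominant distance, vectorized over genotypes
# (x1, x2) vs the reference pair (r1, r2):
#   identical genotypes 0; ii~ij 1; ij~ik 1; ij~kl 2; ii~jk 3; ii~jj 4
gd_locus <- function(x1, x2, r1, r2) {
  same <- (x1 == r1 & x2 == r2) | (x1 == r2 & x2 == r1)
  homX <- x1 == x2
  homR <- r1 == r2
  shareX <- x1 == r1 | x1 == r2 | x2 == r1 | x2 == r2
  d <- ifelse(same, 0,
       ifelse(homX & homR, 4,
       ifelse(homX & !homR, ifelse(shareX, 1, 3),
       ifelse(!homX & homR, ifelse(shareX, 1, 3),
              ifelse(shareX, 1, 2)))))
  d[is.na(x1) | is.na(r1)] <- NA_real_
  d
}

#' Genotypic distance between two multi-locus genotypes
#'
#' Squared codominant genotypic distance: per locus the distance is 0 for
#' identical genotypes, 1 for `ii` vs `ij` or `ij` vs `ik`, 2 for `ij` vs
#' `kl`, 3 for `ii` vs `jk` and 4 for `ii` vs `jj`; the multi-locus value is
#' the sum over loci where both genotypes are present.
#'
#' @param g1,g2 either length-2 integer vectors (one locus) or two-column
#'   matrices with one row per locus.
#' @return non-negative distance; `NA` if no locus is shared.
#' @export
genotypic_distance <- function(g1, g2) {
  if (!is.matrix(g1)) g1 <- matrix(g1, ncol = 2)
  if (!is.matrix(g2)) g2 <- matrix(g2, ncol = 2)
  stopifnot(nrow(g1) == nrow(g2))
  d <- gd_locus(g1[, 1], g1[, 2], g2[, 1], g2[, 2])
  if (all(is.na(d))) return(NA_real_)
  sum(d, na.rm = TRUE)
}

#' Extract a sample's genotype as a loci x 2 matrix
#'
#' @param table a [genotype_table].
#' @param sample_id the sample to extract.
#' @return integer matrix with one row per locus and two allele columns.
#' @export
reference_genotype <- function(table, sample_id) {
  i <- match(sample_id, table$samples$sample_id)
  if (is.na(i)) stop("no such sample: ", sample_id)
  m <- cbind(table$a1[i, ], table$a2[i, ])
  rownames(m) <- table$loci
  m
}

#' Mean genotypic distance to a reference genotype
#'
#' @param table a [genotype_table].
#' @param rows sample indices forming the cell's (re-sampled) trees.
#' @param reference a loci x 2 matrix (see [reference_genotype()]).
#' @return mean multi-locus [genotypic_distance()] from each tree to the
#'   reference.
#' @export
mean_distance_to_reference <- function(table, rows, reference) {
  gd <- per_tree_gd(table, reference)
  mean(gd[rows], na.rm = TRUE)
}

per_tree_gd <- function(table, reference) {
  stopifnot(nrow(reference) == n_loci(table))
  d <- matrix(NA_real_, n_samples(table), n_loci(table))
  for (l in seq_len(n_loci(table)))
    d[, l] <- gd_locus(table$a1[, l], table$a2[, l],
                       reference[l, 1], reference[l, 2])
  rowSums(d, na.rm = TRUE)
}

#' Locally common alleles per cell
#'
#' An allele is locally common when its within-cell frequency exceeds
#' `freq_threshold` (strict) while it is present in at most
#' `occupancy_threshold` of the occupied cells -- a proxy for locally
#' adapted, geographically restricted variants. The occupancy denominator is
#' the number of occupied cells (cells with at least one re-sampled tree),
#' since empty cells carry no frequency information.
#'
#' @param freqs list, one element per cell, each a per-locus list of named
#'   allele-frequency vectors (as built by [compute_cell_stats()]).
#' @param freq_threshold within-cell frequency cutoff (strict `>`, default
#'   0.05).
#' @param occupancy_threshold maximum fraction of occupied cells in which
#'   the allele occurs (inclusive `<=`, default 0.25).
#' @param n_loci number of loci used as the per-locus averaging denominator.
#' @return numeric vector, one value per cell: mean count of locally common
#'   alleles per locus.
#' @export
locally_common_alleles <- function(freqs, freq_threshold = 0.05,
                                   occupancy_threshold = 0.25,
                                   n_loci = length(freqs[[1]])) {
  n_cells_occ <- length(freqs)
  L <- n_loci
  # occupancy per (locus, allele) over occupied cells
  rare <- vector("list", L)
  for (l in seq_len(L)) {
    present <- unlist(lapply(freqs, function(f) names(f[[l]])[f[[l]] > 0]))
    occ <- table(present) / n_cells_occ
    rare[[l]] <- names(occ)[occ <= occupancy_threshold]
  }
  vapply(freqs, function(f) {
    cnt <- 0L
    for (l in seq_len(L)) {
      fl <- f[[l]]
      cnt <- cnt + sum(fl > freq_threshold & names(fl) %in% rare[[l]])
    }
    cnt / L
  }, numeric(1))
}

#' Per-cell diversity statistics
#'
#' Computes, for every occupied cell of a circular-neighborhood assignment,
#' the full set of alpha-diversity statistics: re-sampled tree count, mean
#' alleles per locus (Na), rarefied allelic richness, locally common alleles
#' per locus (LCA), expected and observed heterozygosity (He, Ho), fixation
#' index (F) and, when a reference genotype is supplied, the mean genotypic
#' distance to it (GD). Na and LCA are reported for all occupied cells;
#' the remaining statistics only for cells with at least `min_n` re-sampled
#' trees (others `NA`), matching the study's interpretability threshold.
#'
#' @param assignment a `cell_assignment` from [resample_trees()].
#' @param table the [genotype_table] the assignment was built on.
#' @param min_n minimum re-sampled trees for the sample-size-sensitive
#'   statistics (default 20).
#' @param rarefaction_g gene count for rarefaction (default 40 = 20 diploid
#'   trees).
#' @param reference optional loci x 2 reference genotype matrix (or a
#'   sample_id present in `table`) for the GD column.
#' @param freq_threshold,occupancy_threshold locally-common-allele cutoffs,
#'   see [locally_common_alleles()].
#' @return a data.frame of class `cell_stats` with one row per occupied
#'   cell and columns `cell_id`, `lon`, `lat`, `n_trees`, `na`,
#'   `na_rarefied`, `lca`, `he`, `ho`, `f` and (optionally) `gd_ref`; the
#'   source grid is attached as attribute `"grid"`.
#' @export
compute_cell_stats <- function(assignment, table, min_n = 20,
                               rarefaction_g = 40, reference = NULL,
                               freq_threshold = 0.05,
                               occupancy_threshold = 0.25) {
  stopifnot(inherits(assignment, "cell_assignment"))
  if (is.character(reference) && length(reference) == 1)
    reference <- reference_genotype(table, reference)
  rows_by_cell <- split(assignment$sample, assignment$cell)
  cells <- as.integer(names(rows_by_cell))
  L <- n_loci(table)
  nc <- length(cells)

  gd_tree <- if (!is.null(reference)) per_tree_gd(table, reference)

  n_trees <- integer(nc)
  na <- na_rar <- he <- ho <- f <- gd <- rep(NA_real_, nc)
  freqs <- vector("list", nc)

  for (k in seq_len(nc)) {
    rows <- rows_by_cell[[k]]
    n_trees[k] <- length(rows)
    counts <- allele_counts(table, rows)
    Nl <- vapply(counts, sum, numeric(1))
    has <- Nl > 0
    freqs[[k]] <- lapply(counts, function(cn)
      if (sum(cn) > 0) cn / sum(cn) else stats::setNames(numeric(0), character(0)))
    if (any(has))
      na[k] <- mean(vapply(counts[has], length, integer(1)))
    if (n_trees[k] >= min_n) {
      rr <- vapply(counts[has], rarefied_richness, numeric(1),
                   g = rarefaction_g)
      if (!all(is.na(rr))) na_rar[k] <- mean(rr, na.rm = TRUE)
      he_l <- vapply(counts[has], expected_heterozygosity, numeric(1))
      he[k] <- mean(he_l, na.rm = TRUE)
      het <- table$a1[rows, has, drop = FALSE] != table$a2[rows, has, drop = FALSE]
      ho_l <- colMeans(het, na.rm = TRUE)
      ho[k] <- mean(ho_l[!is.nan(ho_l)])
      f[k] <- fixation_index(he_l, ho_l)
      if (!is.null(reference)) gd[k] <- mean(gd_tree[rows], na.rm = TRUE)
    }
  }

  lca <- locally_common_alleles(freqs, freq_threshold, occupancy_threshold,
                                n_loci = L)
  ctr <- cell_center(assignment$grid, cells)
  out <- data.frame(cell_id = cells, lon = ctr[, "lon"], lat = ctr[, "lat"],
                    n_trees = n_trees, na = na, na_rarefied = na_rar,
                    lca = as.numeric(lca), he = he, ho = ho, f = f)
  if (!is.null(reference)) out$gd_ref <- gd
  attr(out, "grid") <- assignment$grid
  class(out) <- c("cell_stats", "data.frame")
  out
}
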