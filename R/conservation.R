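#' Alleles missing from ex situ collections
#'
#' Partitions the observed alleles by conservation status and returns the
#' in-situ-private alleles: those carried by at least one in situ tree and
#' by no ex situ (genebank) accession. These are the variants an ex situ
#' gap-filling collection should target.
#'
#' @param table a [genotype_table] containing both statuses (if no sample is
#'   ex situ, every allele is missing and a warning is raised).
#' @return a `gap_allele_set`: list with `missing` (data.frame `locus`,
#'   `allele`), `n_total` distinct (locus, allele) pairs observed,
#'   `n_missing`, and `fraction_missing`.
#' @export
exsitu_missing_alleles <- function(table) {
  ex <- table$samples$status == "ex_situ"
  if (!any(ex)) warning("no ex situ samples: every allele is a gap")
  miss <- list(); tot <- 0L
  for (l in seq_along(table$loci)) {
    all_al <- unique(c(table$a1[, l], table$a2[, l]))
    all_al <- sort(all_al[!is.na(all_al)])
    ex_al <- unique(c(table$a1[ex, l], table$a2[ex, l]))
    in_al <- unique(c(table$a1[!ex, l], table$a2[!ex, l]))
    gap <- setdiff(intersect(all_al, in_al), ex_al)
    tot <- tot + length(all_al)
    if (length(gap) > 0)
      miss[[length(miss) + 1L]] <- data.frame(locus = table$loci[l],
                                              allele = gap)
  }
  missing <- if (length(miss) > 0) do.call(rbind, miss) else
    data.frame(locus = character(0), allele = integer(0))
  structure(list(missing = missing, n_total = tot,
                 n_missing = nrow(missing),
                 fraction_missing = if (tot > 0) nrow(missing) / tot else NA_real_),
            class = "gap_allele_set")
}

#' @export
print.gap_allele_set <- function(x, ...) {
  cat(sprintf("gap_allele_set: %d of %d alleles absent ex situ (%.1f%%)\n",
              x$n_missing, x$n_total, 100 * x$fraction_missing))
  invisible(x)
}

#' Richness map of genebank-missing alleles
#'
#' Point-to-grid richness of the in-situ-private alleles: for each occupied
#' cell, the number of distinct missing (locus, allele) pairs carried by its
#' re-sampled trees. High values locate the populations whose variation is
#' least represented ex situ.
#'
#' @param assignment a `cell_assignment` from [resample_trees()].
#' @param table the underlying [genotype_table].
#' @param gaps a `gap_allele_set` from [exsitu_missing_alleles()].
#' @return a [divmap_raster]; occupied cells carry counts (possibly 0),
#'   unoccupied cells are nodata.
#' @export
missing_allele_richness_map <- function(assignment, table, gaps) {
  stopifnot(inherits(assignment, "cell_assignment"),
            inherits(gaps, "gap_allele_set"))
  L <- n_loci(table)
  # per tree, which gap alleles it carries (as locus-offset codes)
  carries <- vector("list", n_samples(table))
  gp <- gaps$missing
  if (nrow(gp) > 0) {
    for (g in seq_len(nrow(gp))) {
      l <- match(gp$locus[g], table$loci)
      hit <- which(table$a1[, l] == gp$allele[g] |
                     table$a2[, l] == gp$allele[g])
      for (i in hit) carries[[i]] <- c(carries[[i]], g)
    }
  }
  rows_by_cell <- split(assignment$sample, assignment$cell)
  cells <- as.integer(names(rows_by_cell))
  vals <- vapply(rows_by_cell, function(rows)
    length(unique(unlist(carries[rows]))), numeric(1))
  r <- divmap_raster(assignment$grid)
  r$values[cells] <- vals
  r
}

#' Climate-envelope distribution scorer
#'
#' Transparent presence-only scorer in the classic bioclim style: the score
#' of a location is the fraction of environmental variables whose value
#' falls inside the `[tail_pct, 100 - tail_pct]` percentile envelope of the
#' presence points. It is a deliberately simple surface for exercising the
#' evaluation pipeline; any externally modeled raster (e.g. a Maxent
#' output) can be supplied instead wherever a surface is needed.
#'
#' @param presence_env numeric matrix, presence points x environmental
#'   variables (>= 2 points).
#' @param tail_pct percentile trimmed from each tail of each variable's
#'   envelope (default 0 = min/max envelope).
#' @return an `envelope_sdm` model; score new points with `predict(model,
#'   newdata)` where `newdata` is a matrix with matching columns.
#' @export
envelope_sdm <- function(presence_env, tail_pct = 0) {
  presence_env <- as.matrix(presence_env)
  if (nrow(presence_env) < 2) stop("need at least 2 presence points")
  lo <- apply(presence_env, 2, stats::quantile, probs = tail_pct / 100,
              na.rm = TRUE, names = FALSE)
  hi <- apply(presence_env, 2, stats::quantile,
              probs = 1 - tail_pct / 100, na.rm = TRUE, names = FALSE)
  structure(list(lo = lo, hi = hi, tail_pct = tail_pct,
                 vars = colnames(presence_env)),
            class = "envelope_sdm")
}

#' @param object an `envelope_sdm` model.
#' @param newdata points x variables matrix (columns in training order).
#' @param ... ignored.
#' @rdname envelope_sdm
#' @export
predict.envelope_sdm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$lo))
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         length(object$lo))
  inside <- sweep(newdata, 2, object$lo, ">=") &
    sweep(newdata, 2, object$hi, "<=")
  rowMeans(inside)
}

#' Ten-percentile training presence threshold
#'
#' The score cutoff below which `pct` percent of the training presence
#' points fall; binarizing a surface at this threshold excludes the
#' lowest-scoring `pct`% of presences. With `pct = 0` it reduces to the
#' minimum training presence score.
#'
#' @param scores training presence scores (non-empty).
#' @param pct percent of presences allowed below the threshold (default 10).
#' @return the threshold score; cells with `score >= threshold` are modeled
#'   present.
#' @export
training_presence_threshold <- function(scores, pct = 10) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no training scores supplied")
  s <- sort(scores)
  k <- floor(length(s) * pct / 100)
  s[min(k + 1L, length(s))]
}

#' Uniform pseudo-absence points
#'
#' Random background points standing in for true absences when evaluating a
#' presence-only model: uniform draws in the presence bounding box expanded
#' by `expand` times its width/height on each side, `factor` times as many
#' points as presences. Reproducible given `seed`.
#'
#' @param presences two-column lon/lat matrix or data.frame (>= 2 points,
#'   non-degenerate bounding box).
#' @param factor pseudo-absences per presence (default 5).
#' @param expand fractional bounding-box expansion per side (default 0.1).
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat`.
#' @export
generate_pseudo_absences <- function(presences, factor = 5, expand = 0.1,
                                     seed = 1) {
  p <- as.matrix(presences)[, 1:2, drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 presence points")
  rx <- range(p[, 1]); ry <- range(p[, 2])
  if (diff(rx) == 0 || diff(ry) == 0)
    stop("degenerate presence bounding box")
  ex <- expand * diff(rx); ey <- expand * diff(ry)
  n <- factor * nrow(p)
  set.seed(seed)
  data.frame(lon = stats::runif(n, rx[1] - ex, rx[2] + ex),
             lat = stats::runif(n, ry[1] - ey, ry[2] + ey))
}

#' Seeded train/test split
#'
#' @param n number of points.
#' @param test_fraction fraction held out for testing (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, test_fraction = 0.2, seed = 1) {
  set.seed(seed)
  test <- sort(sample.int(n, size = round(n * test_fraction)))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Rank-based AUC
#'
#' Probability that a random presence outscores a random absence, with ties
#' counted one half -- the Mann-Whitney form of the area under the ROC
#' curve, threshold-free.
#'
#' @param presence_scores,absence_scores numeric score vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(presence_scores, absence_scores) {
  p <- presence_scores[!is.na(presence_scores)]
  a <- absence_scores[!is.na(absence_scores)]
  if (length(p) == 0 || length(a) == 0) stop("both score lists must be non-empty")
  r <- rank(c(p, a))
  (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
    (length(p) * length(a))
}

#' Cohen's kappa of a binarized distribution surface
#'
#' Chance-corrected agreement between the binary prediction
#' (`score >= threshold`) and the presence/absence labels. When no
#' threshold is given, kappa is maximized over all candidate thresholds
#' (the observed scores), and the maximizing threshold is attached as
#' attribute `"threshold"`.
#'
#' @param presence_scores,absence_scores numeric score vectors.
#' @param threshold optional score cutoff.
#' @return kappa in `[-1, 1]`.
#' @export
evaluate_kappa <- function(presence_scores, absence_scores,
                           threshold = NULL) {
  p <- presence_scores[!is.na(presence_scores)]
  a <- absence_scores[!is.na(absence_scores)]
  if (length(p) == 0 || length(a) == 0) stop("both score lists must be non-empty")
  kappa_at <- function(t) {
    tp <- sum(p >= t); fn <- length(p) - tp
    fp <- sum(a >= t); tn <- length(a) - fp
    n <- tp + fn + fp + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    if (pe == 1) return(0)
    (po - pe) / (1 - pe)
  }
  if (!is.null(threshold)) return(kappa_at(threshold))
  cand <- sort(unique(c(p, a)))
  ks <- vapply(cand, kappa_at, numeric(1))
  best <- which.max(ks)
  structure(ks[best], threshold = cand[best])
}

#' Sampling coverage of a modeled distribution
#'
#' Classifies the modeled-present cells of a distribution surface by how
#' well the genetic sampling covered them: well-sampled (`>= min_n`
#' re-sampled trees), under-sampled (1 to `min_n - 1`), or unsampled gaps
#' (0 trees). The three percentages always sum to 100.
#'
#' @param binary_distribution [divmap_raster] with 1 for modeled presence
#'   (0 or nodata elsewhere).
#' @param counts [divmap_raster] of re-sampled tree counts on the same
#'   grid (nodata = 0 trees).
#' @param min_n well-sampled threshold (default 20).
#' @return a `coverage_report`: list with `pct_well_sampled`,
#'   `pct_under_sampled`, `pct_gap` and `n_modeled_cells`.
#' @export
sampling_coverage <- function(binary_distribution, counts, min_n = 20) {
  g1 <- binary_distribution$grid; g2 <- counts$grid
  if (!isTRUE(all.equal(unclass(g1), unclass(g2))))
    stop("distribution and count rasters are on different grids")
  modeled <- which(!is.na(binary_distribution$values) &
                     binary_distribution$values > 0)
  if (length(modeled) == 0) stop("no modeled-present cells")
  n <- counts$values[modeled]
  n[is.na(n)] <- 0
  out <- list(pct_well_sampled = 100 * mean(n >= min_n),
              pct_under_sampled = 100 * mean(n >= 1 & n < min_n),
              pct_gap = 100 * mean(n == 0),
              n_modeled_cells = length(modeled))
  class(out) <- "coverage_report"
  out
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(paste0("coverage_report over %d modeled cells: ",
                     "%.1f%% well sampled, %.1f%% under-sampled, ",
                     "%.1f%% unsampled gap\n"),
              x$n_modeled_cells, x$pct_well_sampled, x$pct_under_sampled,
              x$pct_gap))
  invisible(x)
}
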