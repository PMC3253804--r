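# internal: per-locus allele-index encoding of a genotype table.
# Returns list(levels = per-locus allele labels, idx = list per locus of
# n x 2 integer matrices of allele indices, NA for missing).
encode_alleles <- function(table) {
  L <- n_loci(table)
  levels <- vector("list", L)
  idx <- vector("list", L)
  for (l in seq_len(L)) {
    lev <- sort(unique(c(table$a1[, l], table$a2[, l])))
    lev <- lev[!is.na(lev)]
    levels[[l]] <- lev
    idx[[l]] <- cbind(match(table$a1[, l], lev), match(table$a2[, l], lev))
  }
  list(levels = levels, idx = idx)
}

#' Admixture model log-likelihood
#'
#' Log-likelihood of a genotype table under the admixture model: each
#' allele copy of individual i at locus l is drawn from cluster k with
#' probability `Q[i, k]` and is allele a with probability `P[[l]][k, a]`, so
#' `logL = sum over copies log( sum_k Q[i,k] * P[[l]][k, a] )`. Missing
#' genotypes are skipped.
#'
#' @param Q n x K matrix of individual membership proportions (rows sum
#'   to 1).
#' @param P list, one element per locus: K x (alleles at locus) frequency
#'   matrix (rows sum to 1), columns named by allele label.
#' @param table a [genotype_table].
#' @return the log-likelihood (scalar). A zero-probability observed allele
#'   under every cluster is a hard error; the EM fitter prevents it by
#'   flooring frequencies.
#' @export
admixture_loglik <- function(Q, P, table) {
  enc <- encode_alleles(table)
  ll <- 0
  for (l in seq_len(n_loci(table))) {
    Pl <- P[[l]]
    for (c in 1:2) {
      a <- enc$idx[[l]][, c]
      ok <- !is.na(a)
      if (!any(ok)) next
      lik <- rowSums(Q[ok, , drop = FALSE] * t(Pl)[a[ok], , drop = FALSE])
      if (any(lik <= 0))
        stop("zero-probability allele under all clusters at locus ",
             table$loci[l], "; floor the frequencies")
      ll <- ll + sum(log(lik))
    }
  }
  ll
}

#' Fit the admixture model by EM with random restarts
#'
#' Maximum-likelihood analogue of model-based Bayesian admixture
#' clustering: EM alternates updating individual membership proportions Q
#' and per-cluster allele frequencies P until the log-likelihood gain drops
#' below `tol`. The log-likelihood is non-decreasing across iterations;
#' frequencies are floored at `1e-6` and renormalized so private alleles
#' never produce infinite penalties. Multiple random restarts guard against
#' local maxima; results are returned sorted by final log-likelihood, best
#' first, and are fully reproducible from `seed`.
#'
#' @param table a [genotype_table].
#' @param K number of ancestral clusters (>= 1).
#' @param n_runs independent restarts (default 20).
#' @param max_iter iteration cap per run (default 200).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-4).
#' @param seed integer seed; run r uses `seed + r`.
#' @return list of `admixture_result` objects (fields `K`, `Q`, `P`,
#'   `loglik`, `seed`, `iterations`, `converged`), sorted by `loglik`
#'   decreasing.
#' @export
fit_admixture_em <- function(table, K, n_runs = 20, max_iter = 200,
                             tol = 1e-4, seed = 1) {
  stopifnot(K >= 1, n_samples(table) > 0)
  enc <- encode_alleles(table)
  n <- n_samples(table)
  L <- n_loci(table)
  n_alleles <- vapply(enc$levels, length, integer(1))

  pooled <- lapply(seq_len(L), function(l) {
    cn <- tabulate(c(enc$idx[[l]]), nbins = n_alleles[l])
    p <- cn / sum(cn)
    floor_renorm(p)
  })

  # copies of non-missing genotypes per individual (Q-update denominator)
  copies_i <- rowSums(2 * !is.na(table$a1))

  one_run <- function(run_seed) {
    set.seed(run_seed)
    if (K == 1) {
      Q <- matrix(1, n, 1)
      P <- lapply(pooled, function(p) matrix(p, 1,
                    dimnames = list(NULL, NULL)))
      ll <- admixture_loglik_enc(Q, P, enc, L)
      return(structure(list(K = 1L, Q = Q, P = name_P(P, enc),
                            loglik = ll, seed = run_seed, iterations = 1L,
                            converged = TRUE), class = "admixture_result"))
    }
    g <- matrix(stats::rgamma(n * K, 1), n, K)     # symmetric Dirichlet(1)
    Q <- g / rowSums(g)
    P <- lapply(pooled, function(p) {
      m <- matrix(rep(p, each = K), K) *
        matrix(stats::runif(K * length(p), 0.5, 1.5), K)
      t(apply(m, 1, floor_renorm))
    })
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      Qnum <- matrix(0, n, K)
      Pnum <- lapply(n_alleles, function(a) matrix(0, K, a))
      ll <- 0
      for (l in seq_len(L)) {
        PT <- t(P[[l]])                      # alleles x K
        for (cc in 1:2) {
          a <- enc$idx[[l]][, cc]
          ok <- which(!is.na(a))
          if (length(ok) == 0) next
          W <- PT[a[ok], , drop = FALSE]     # n_ok x K
          R <- Q[ok, , drop = FALSE] * W
          den <- rowSums(R)
          ll <- ll + sum(log(den))
          R <- R / den
          Qnum[ok, ] <- Qnum[ok, ] + R
          rs <- rowsum(R, group = a[ok])   # alleles-present x K, sorted
          cols <- as.integer(rownames(rs))
          Pnum[[l]][, cols] <- Pnum[[l]][, cols] + t(rs)
        }
      }
      Q <- Qnum / pmax(copies_i, 1)
      Q[copies_i == 0, ] <- 1 / K
      P <- lapply(Pnum, function(m) t(apply(m, 1, floor_renorm)))
      if (is.finite(ll_old) && ll - ll_old < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
    }
    ll <- admixture_loglik_enc(Q, P, enc, L)
    if (!converged)
      warning("EM run (seed ", run_seed, ") hit max_iter without converging")
    structure(list(K = as.integer(K), Q = Q, P = name_P(P, enc),
                   loglik = ll, seed = run_seed, iterations = iter,
                   converged = converged), class = "admixture_result")
  }

  runs <- lapply(seq_len(n_runs), function(r) one_run(seed + r))
  runs[order(vapply(runs, function(x) x$loglik, numeric(1)),
             decreasing = TRUE)]
}

floor_renorm <- function(p, floor = 1e-6) {
  p <- pmax(p, floor)
  p / sum(p)
}

name_P <- function(P, enc) {
  for (l in seq_along(P)) colnames(P[[l]]) <- as.character(enc$levels[[l]])
  P
}

admixture_loglik_enc <- function(Q, P, enc, L) {
  ll <- 0
  for (l in seq_len(L)) {
    PT <- t(P[[l]])
    for (cc in 1:2) {
      a <- enc$idx[[l]][, cc]
      ok <- which(!is.na(a))
      if (length(ok) == 0) next
      ll <- ll + sum(log(rowSums(Q[ok, , drop = FALSE] *
                                   PT[a[ok], , drop = FALSE])))
    }
  }
  ll
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K = %d, logL = %.2f, %d iterations%s\n",
              x$K, x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit the admixture model over a range of K
#'
#' Convenience scan used for model choice: runs [fit_admixture_em()] for
#' each K and collects the per-run log-likelihoods for [evanno_delta_k()].
#'
#' @param table a [genotype_table].
#' @param K_range integer vector of K values (default 1:10, contiguous).
#' @param ... passed to [fit_admixture_em()] (`n_runs`, `seed`, ...).
#' @return list with `best` (best run per K), `loglik` (runs x K matrix)
#'   and `K_range`.
#' @export
admixture_scan <- function(table, K_range = 1:10, ...) {
  runs <- lapply(K_range, function(K) fit_admixture_em(table, K, ...))
  ll <- vapply(runs, function(rs) vapply(rs, function(x) x$loglik,
                                         numeric(1)),
               numeric(length(runs[[1]])))
  colnames(ll) <- as.character(K_range)
  list(best = lapply(runs, `[[`, 1), loglik = ll, K_range = K_range)
}

#' Evanno delta-K cluster-number choice
#'
#' The second-order rate of change of the log-likelihood across K,
#' normalized by the between-run standard deviation:
#' `L'(K) = meanL(K) - meanL(K-1)` and
#' `deltaK(K) = |L'(K+1) - L'(K)| / sd(L(K))`. Defined only for interior K;
#' the selected cluster number is the K maximizing deltaK. A zero standard
#' deviation leaves deltaK undefined at that K (excluded from the argmax
#' with a warning).
#'
#' @param loglik runs x K matrix of log-likelihoods (column names = K), as
#'   returned by [admixture_scan()], or a list of per-K log-likelihood
#'   vectors.
#' @param K_range the (contiguous) K values; defaults to column names.
#' @return a `delta_k_table` data.frame with columns `K`, `mean_loglik`,
#'   `sd_loglik`, `delta_k`, and the chosen K as attribute `"best_k"`.
#' @export
evanno_delta_k <- function(loglik, K_range = NULL) {
  if (is.list(loglik) && !is.data.frame(loglik)) {
    if (is.null(K_range)) K_range <- as.integer(names(loglik))
    mean_l <- vapply(loglik, mean, numeric(1))
    sd_l <- vapply(loglik, stats::sd, numeric(1))
  } else {
    if (is.null(K_range)) K_range <- as.integer(colnames(loglik))
    mean_l <- colMeans(loglik)
    sd_l <- apply(loglik, 2, stats::sd)
  }
  if (any(diff(K_range) != 1)) stop("K_range must be contiguous")
  nk <- length(K_range)
  if (nk < 3) stop("delta-K needs at least three consecutive K values")
  lp <- c(NA, diff(mean_l))                      # L'(K)
  lpp <- c(NA, abs(diff(lp)[-1]), NA)            # |L'(K+1) - L'(K)| at interior K
  dk <- lpp / sd_l
  dk[c(1, nk)] <- NA
  if (any(!is.na(lpp) & sd_l == 0)) {
    warning("zero run-to-run sd at some K; delta-K undefined there")
    dk[sd_l == 0] <- NA
  }
  out <- data.frame(K = K_range, mean_loglik = mean_l, sd_loglik = sd_l,
                    delta_k = dk)
  rownames(out) <- NULL
  best <- if (all(is.na(dk))) NA_integer_ else K_range[which.max(dk)]
  attr(out, "best_k") <- best
  class(out) <- c("delta_k_table", "data.frame")
  out
}

#' Map mean cluster-membership probability per grid cell
#'
#' @param assignment a `cell_assignment` from [resample_trees()].
#' @param Q n x K membership matrix from the best run at the selected K
#'   (sample order = table order the assignment was built on).
#' @param cluster cluster column to map.
#' @param min_n minimum re-sampled trees per cell (default 20; smaller
#'   cells are nodata).
#' @return a [divmap_raster] of per-cell mean membership probabilities; the
#'   per-cluster rasters sum to 1 at every valued cell.
#' @export
map_cluster_probability <- function(assignment, Q, cluster, min_n = 20) {
  stopifnot(inherits(assignment, "cell_assignment"))
  q <- Q[assignment$sample, cluster]
  s <- rowsum(q, assignment$cell)
  cnt <- tabulate(assignment$cell, nbins = n_cells(assignment$grid))
  r <- divmap_raster(assignment$grid)
  ids <- as.integer(rownames(s))
  keep <- cnt[ids] >= min_n
  r$values[ids[keep]] <- s[keep, 1] / cnt[ids[keep]]
  r
}
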