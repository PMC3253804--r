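# small in-code fixtures shared across the suite

# build a genotype_table from allele matrices with minimal ceremony
mk_table <- function(a1, a2, lon = NULL, lat = NULL, status = "in_situ",
                     loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1)
  if (is.null(lon)) lon <- seq(-79, -78, length.out = n)
  if (is.null(lat)) lat <- seq(-5, -4, length.out = n)
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(a1)))
  genotype_table(
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               lon = lon, lat = lat,
               status = rep_len(status, n), stringsAsFactors = FALSE),
    loci, a1, a2)
}

# random diploid table: n samples, L loci, A alleles per locus
rand_table <- function(n, L = 3, A = 4, seed = 1) {
  set.seed(seed)
  a1 <- matrix(sample.int(A, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample.int(A, n * L, replace = TRUE), n, L)
  mk_table(a1, a2)
}

# independent oracle for the squared codominant genotypic distance:
# half the squared euclidean distance between allele-count vectors
gd_oracle <- function(g1, g2) {
  if (!is.matrix(g1)) g1 <- matrix(g1, ncol = 2)
  if (!is.matrix(g2)) g2 <- matrix(g2, ncol = 2)
  tot <- 0; seen <- FALSE
  for (l in seq_len(nrow(g1))) {
    if (anyNA(g1[l, ]) || anyNA(g2[l, ])) next
    seen <- TRUE
    al <- sort(unique(c(g1[l, ], g2[l, ])))
    x <- tabulate(match(g1[l, ], al), length(al))
    y <- tabulate(match(g2[l, ], al), length(al))
    tot <- tot + 0.5 * sum((x - y)^2)
  }
  if (seen) tot else NA_real_
}

# exhaustive pairwise AUC oracle
auc_brute <- function(pres, abs) {
  cmp <- outer(pres, abs, function(p, a) (p > a) + 0.5 * (p == a))
  mean(cmp)
}

# Monte-Carlo rarefaction oracle: mean distinct alleles in g genes drawn
# without replacement, plus its standard error
mc_rarefaction <- function(counts, g, draws = 1e5) {
  pool <- rep(seq_along(counts), counts)
  x <- replicate(draws, length(unique(sample(pool, g))))
  c(mean = mean(x), se = stats::sd(x) / sqrt(draws))
}
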