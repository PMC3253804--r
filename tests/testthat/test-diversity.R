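test_that("mean alleles per locus averages distinct alleles over loci", {
  # one tree homozygous everywhere -> 1; heterozygous everywhere -> 2
  n <- 9
  hom <- mk_table(matrix(1L, 1, n), matrix(1L, 1, n))
  het <- mk_table(matrix(1L, 1, n), matrix(2L, 1, n))
  expect_equal(mean_alleles_per_locus(allele_counts(hom)), 1)
  expect_equal(mean_alleles_per_locus(allele_counts(het)), 2)
  counts <- list(L1 = c(a = 3L, b = 1L), L2 = c(c = 4L))
  expect_equal(mean_alleles_per_locus(counts), 1.5)
  expect_warning(mean_alleles_per_locus(list(c(a = 2L), integer(0))),
                 "no data")
})

test_that("hypergeometric rarefaction matches the combinatorial value", {
  # counts {a:30, b:10}, g = 2:
  # [1 - C(10,2)/C(40,2)] + [1 - C(30,2)/C(40,2)] = 1080/780
  expect_equal(rarefied_richness(c(a = 30, b = 10), g = 2), 1080 / 780)
  # rarefying to the full sample returns the observed allele count
  expect_equal(rarefied_richness(c(5, 3, 2), g = 10), 3)
  # a monomorphic locus is always 1
  expect_equal(rarefied_richness(c(99), g = 40), 1)
  expect_true(is.na(rarefied_richness(c(10, 10), g = 40)))
})

test_that("rarefaction agrees with Monte-Carlo subsampling on small cells", {
  set.seed(11)
  for (rep in 1:6) {
    k <- sample(2:3, 1)
    counts <- sample(1:6, k, replace = TRUE)
    N <- sum(counts)
    g <- sample(2:max(2, N - 1), 1)
    mc <- mc_rarefaction(counts, g, draws = 1e5)
    expect_lt(abs(rarefied_richness(counts, g) - mc["mean"]),
              3 * mc["se"] + 1e-9)
  }
})

test_that("rarefied richness never exceeds Na and grows with g", {
  set.seed(12)
  for (rep in 1:20) {
    counts <- sample(1:30, sample(2:6, 1), replace = TRUE)
    gs <- seq(2, sum(counts), length.out = 5)
    vals <- vapply(gs, function(g) rarefied_richness(counts, floor(g)),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    expect_lte(vals[length(vals)], length(counts) + 1e-12)
  }
})

test_that("expected heterozygosity follows 1 - sum(p^2)", {
  expect_equal(expected_heterozygosity(c(10, 10)), 0.5)
  expect_equal(expected_heterozygosity(c(7)), 0)
  expect_equal(expected_heterozygosity(c(5, 5, 5, 5)), 0.75)
  # invariant under allele relabeling
  set.seed(13)
  cn <- c(a = 4L, b = 9L, c = 1L)
  expect_equal(expected_heterozygosity(cn),
               expected_heterozygosity(rev(cn)))
})

test_that("observed heterozygosity counts mixed-allele genotypes", {
  a1 <- matrix(1L, 2, 3); a2 <- matrix(c(1L, 2L), 2, 3)
  tab <- mk_table(a1, a2)     # tree 1 all hom, tree 2 all het
  expect_equal(observed_heterozygosity(tab, 1), 0)
  expect_equal(observed_heterozygosity(tab, 2), 1)
  expect_equal(observed_heterozygosity(tab), 0.5)
})

test_that("fixation index averages over polymorphic loci only", {
  expect_equal(fixation_index(0.5, 0.5), 0)
  expect_equal(fixation_index(0.5, 0), 1)
  expect_equal(fixation_index(0.5, 1), -1)
  expect_equal(fixation_index(c(0, 0.5), c(0, 0.25)), 0.5)
  expect_true(is.na(fixation_index(c(0, 0), c(0, 0))))
})

test_that("genotypic distance matches the allele-count oracle", {
  expect_equal(genotypic_distance(c(1, 1), c(1, 1)), 0)
  expect_equal(genotypic_distance(c(1, 1), c(2, 2)), 4)
  expect_equal(genotypic_distance(c(1, 2), c(1, 3)), 1)
  expect_equal(genotypic_distance(c(1, 1), c(1, 2)), 1)
  expect_equal(genotypic_distance(c(1, 2), c(3, 4)), 2)
  expect_equal(genotypic_distance(c(1, 1), c(2, 3)), 3)
  set.seed(14)
  for (rep in 1:200) {
    g1 <- sample(1:4, 2, replace = TRUE)
    g2 <- sample(1:4, 2, replace = TRUE)
    expect_equal(genotypic_distance(g1, g2), gd_oracle(g1, g2))
    # symmetric in its arguments
    expect_equal(genotypic_distance(g1, g2), genotypic_distance(g2, g1))
  }
  # multi-locus: sum over loci, invariant under locus permutation
  m1 <- matrix(sample(1:4, 18, replace = TRUE), 9)
  m2 <- matrix(sample(1:4, 18, replace = TRUE), 9)
  expect_equal(genotypic_distance(m1, m2), gd_oracle(m1, m2))
  p <- sample(9)
  expect_equal(genotypic_distance(m1[p, ], m2[p, ]),
               genotypic_distance(m1, m2))
  # missing loci are skipped
  m1[3, ] <- NA
  expect_equal(genotypic_distance(m1, m2), gd_oracle(m1, m2))
})

test_that("mean distance to an all-homozygote reference is 4 per locus", {
  L <- 9
  tab <- mk_table(matrix(1L, 5, L), matrix(1L, 5, L))
  ref <- matrix(2L, L, 2)
  expect_equal(mean_distance_to_reference(tab, 1:5, ref), 36)
  expect_equal(mean_distance_to_reference(tab, 1:5,
                                          cbind(rep(1L, L), rep(1L, L))), 0)
})

test_that("locally common alleles need >5% frequency in <=25% of cells", {
  # allele "b" occurs in 1 of 4 occupied cells (occupancy 0.25, inclusive)
  freqs <- list(
    list(L1 = c("1" = 0.9, "b" = 0.1)),
    list(L1 = c("1" = 1)),
    list(L1 = c("1" = 1)),
    list(L1 = c("1" = 1)))
  expect_equal(locally_common_alleles(freqs, n_loci = 1), c(1, 0, 0, 0))
  # present everywhere -> occupancy 1 -> never counted
  freqs2 <- lapply(1:4, function(i) list(L1 = c("1" = 0.5, "b" = 0.5)))
  expect_equal(locally_common_alleles(freqs2, n_loci = 1), rep(0, 4))
  # frequency exactly at the threshold is NOT counted (strict >)
  freqs3 <- list(list(L1 = c("1" = 0.95, "b" = 0.05)),
                 list(L1 = c("1" = 1)), list(L1 = c("1" = 1)),
                 list(L1 = c("1" = 1)))
  expect_equal(locally_common_alleles(freqs3, n_loci = 1), rep(0, 4))
})

test_that("cell statistics respect the 20-tree threshold and invariants", {
  set.seed(15)
  sim <- simulate_landscape(landscape_config(
    n_trees = 400, extent = c(-79, -75, -8, -4), n_hubs = 5,
    clonal_patch = NULL, hotspot = NULL, withhold_hotspot = FALSE,
    inbreeding_region = NULL, seed = 15))
  grid <- make_grid(c(range(sim$table$samples$lon),
                      range(sim$table$samples$lat)))
  asn <- resample_trees(sim$table, grid, neighborhood_mask())
  st <- compute_cell_stats(asn, sim$table, reference = sim$reference)
  expect_s3_class(st, "cell_stats")
  small <- st$n_trees < 20
  expect_true(any(small) && any(!small))
  expect_true(all(is.na(st$he[small])))
  expect_true(all(is.na(st$na_rarefied[small])))
  expect_true(all(is.na(st$gd_ref[small])))
  expect_true(all(!is.na(st$na)))
  big <- !small
  expect_true(all(st$na_rarefied[big] <= st$na[big] + 1e-9))
  expect_true(all(st$he[big] >= 0 & st$he[big] <= 1))
  expect_true(all(st$ho[big] >= 0 & st$ho[big] <= 1))
  # F consistency with its definition on a monomorphic-free cell
  expect_true(all(st$gd_ref[big] >= 0))
})

test_that("duplicating every tree in a cell leaves frequencies-based stats fixed", {
  tab <- rand_table(12, L = 4, A = 5, seed = 16)
  rows <- 1:12
  counts1 <- allele_counts(tab, rows)
  counts2 <- allele_counts(tab, c(rows, rows))
  expect_equal(mean_alleles_per_locus(counts2),
               mean_alleles_per_locus(counts1))
  expect_equal(expected_heterozygosity(counts2),
               expected_heterozygosity(counts1))
  expect_equal(observed_heterozygosity(tab, c(rows, rows)),
               observed_heterozygosity(tab, rows))
  # rarefied richness changes only through the doubled gene count
  expect_equal(rarefied_richness(counts2[[1]], g = 2 * sum(counts1[[1]])),
               length(counts1[[1]]))
})
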