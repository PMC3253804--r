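test_that("in-situ-private alleles are the set difference by status", {
  # ex situ carries {1,2}; in situ carries {1,2,3}
  a1 <- matrix(c(1L, 1L, 3L), 3, 1)
  a2 <- matrix(c(2L, 2L, 1L), 3, 1)
  tab <- mk_table(a1, a2, status = c("ex_situ", "in_situ", "in_situ"))
  gaps <- exsitu_missing_alleles(tab)
  expect_equal(gaps$missing$allele, 3L)
  expect_equal(gaps$n_total, 3L)
  expect_equal(gaps$fraction_missing, 1 / 3)
  # identical allele sets -> empty
  tab2 <- mk_table(matrix(1L, 2, 1), matrix(2L, 2, 1),
                   status = c("ex_situ", "in_situ"))
  expect_equal(exsitu_missing_alleles(tab2)$n_missing, 0L)
  # no ex situ samples: everything missing, with a warning
  tab3 <- mk_table(matrix(1L, 2, 1), matrix(2L, 2, 1))
  expect_warning(g3 <- exsitu_missing_alleles(tab3), "no ex situ")
  expect_equal(g3$n_missing, g3$n_total)
})

test_that("missing-allele richness is confined to carrier cells and bounded", {
  # two spatial groups far apart; gap alleles 8 and 9 only in the east group
  n <- 24
  lon <- c(rep(-79.5, 12), rep(-76.5, 12))
  lat <- rep(-5.5, 24)
  a1 <- matrix(1L, n, 2); a2 <- matrix(2L, n, 2)
  a1[13:24, 1] <- 8L       # gap allele at locus 1, east only
  a1[13:24, 2] <- 9L
  tab <- mk_table(a1, a2, lon = lon, lat = lat,
                  status = c(rep("ex_situ", 6), rep("in_situ", 18)))
  gaps <- exsitu_missing_alleles(tab)
  expect_setequal(gaps$missing$allele, c(8L, 9L))
  grid <- make_grid(c(-80, -76, -6, -5))
  asn <- resample_trees(tab, grid, neighborhood_mask())
  r <- missing_allele_richness_map(asn, tab, gaps)
  ctr <- cell_center(asn$grid, which(!is.na(r$values) & r$values > 0))
  expect_true(all(ctr[, "lon"] > -78))          # east region only
  expect_true(all(r$values <= gaps$n_missing, na.rm = TRUE))
  # occupied western cells are 0, not NA
  west <- which(!is.na(r$values) & r$values == 0)
  expect_gt(length(west), 0)
  # no gaps -> all-zero over occupied cells
  tab0 <- mk_table(matrix(1L, 4, 1), matrix(2L, 4, 1),
                   status = c("ex_situ", rep("in_situ", 3)))
  asn0 <- resample_trees(tab0, make_grid(c(-80, -78, -6, -4)),
                         neighborhood_mask())
  r0 <- missing_allele_richness_map(asn0, tab0, exsitu_missing_alleles(tab0))
  expect_true(all(r0$values[!is.na(r0$values)] == 0))
})

test_that("the climate envelope scores the fraction of variables inside", {
  set.seed(41)
  env <- matrix(runif(40), 20, 2)
  model <- envelope_sdm(env, tail_pct = 0)
  expect_equal(predict(model, env), rep(1, 20))   # presences score 1
  expect_equal(predict(model, cbind(10, 10)), 0)  # outside every envelope
  expect_equal(predict(model, cbind(0.5, 10)), 0.5)
  # a 19-variable point inside 10 envelopes scores 10/19
  env19 <- matrix(runif(19 * 10, 0.4, 0.6), 10, 19)
  m19 <- envelope_sdm(env19)
  pt <- c(rep(0.5, 10), rep(5, 9))
  expect_equal(predict(m19, matrix(pt, 1)), 10 / 19)
})

test_that("training presence threshold drops the lowest pct of presences", {
  scores <- seq(0.1, 1, by = 0.1)
  expect_equal(training_presence_threshold(scores, pct = 10), 0.2)
  expect_equal(training_presence_threshold(scores, pct = 0), 0.1)
  expect_equal(training_presence_threshold(rep(0.7, 5), pct = 10), 0.7)
})

test_that("pseudo-absences fill the expanded bounding box reproducibly", {
  set.seed(42)
  pres <- cbind(runif(20, -79, -75), runif(20, -10, -6))
  pa <- generate_pseudo_absences(pres, factor = 5, expand = 0.1, seed = 7)
  expect_equal(nrow(pa), 100L)
  rx <- range(pres[, 1]); ry <- range(pres[, 2])
  expect_true(all(pa$lon >= rx[1] - 0.1 * diff(rx) - 1e-12 &
                    pa$lon <= rx[2] + 0.1 * diff(rx) + 1e-12))
  expect_true(all(pa$lat >= ry[1] - 0.1 * diff(ry) - 1e-12 &
                    pa$lat <= ry[2] + 0.1 * diff(ry) + 1e-12))
  expect_identical(pa, generate_pseudo_absences(pres, factor = 5,
                                                expand = 0.1, seed = 7))
  expect_error(generate_pseudo_absences(cbind(c(1, 1), c(2, 3))),
               "degenerate")
})

test_that("rank AUC equals exhaustive pairwise comparison", {
  expect_equal(evaluate_auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(evaluate_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  set.seed(43)
  for (rep in 1:10) {
    p <- round(runif(sample(3:50, 1)), 2)
    a <- round(runif(sample(3:50, 1)), 2)
    expect_equal(evaluate_auc(p, a), auc_brute(p, a))
  }
})

test_that("kappa matches the confusion-matrix formula and its extremes", {
  # TP=45, FN=5, FP=10, TN=40 at threshold 0.5 -> (0.85 - 0.5) / 0.5 = 0.70
  p <- c(rep(0.9, 45), rep(0.1, 5))
  a <- c(rep(0.9, 10), rep(0.1, 40))
  expect_equal(evaluate_kappa(p, a, threshold = 0.5), 0.70)
  expect_equal(evaluate_kappa(c(1, 1), c(0, 0), threshold = 0.5), 1)
  # prediction independent of truth -> 0
  expect_equal(evaluate_kappa(c(1, 0), c(1, 0), threshold = 0.5), 0)
  # maximized kappa reports its threshold
  k <- evaluate_kappa(c(0.8, 0.9, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(as.numeric(k), 1)
  expect_equal(attr(k, "threshold"), 0.4)
})

test_that("coverage classes partition the modeled area", {
  g <- grid_spec(0, 0, 1, 5, 2)
  model <- divmap_raster(g, c(rep(1, 10)))
  counts <- divmap_raster(g, c(25, 30, 20, 40, 50, 5, 19, NA, NA, NA))
  cov <- sampling_coverage(model, counts, min_n = 20)
  expect_equal(cov$pct_well_sampled, 50)
  expect_equal(cov$pct_under_sampled, 20)
  expect_equal(cov$pct_gap, 30)
  expect_equal(cov$pct_well_sampled + cov$pct_under_sampled + cov$pct_gap,
               100)
  # all cells well sampled
  cov2 <- sampling_coverage(model, divmap_raster(g, rep(99, 10)))
  expect_equal(cov2$pct_well_sampled, 100)
  # raising min_n never increases the well-sampled share
  for (m in c(5, 20, 40, 60)) {
    cv <- sampling_coverage(model, counts, min_n = m)
    if (m > 5) expect_lte(cv$pct_well_sampled, prev)
    prev <- cv$pct_well_sampled
  }
  # grid mismatch is a hard error
  g2 <- grid_spec(0, 0, 1, 2, 5)
  expect_error(sampling_coverage(model, divmap_raster(g2, rep(1, 10))),
               "different grids")
})

test_that("train/test split is disjoint, exhaustive and seeded", {
  sp <- train_test_split(100, 0.2, seed = 9)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_identical(sp, train_test_split(100, 0.2, seed = 9))
})
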