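test_that("admixture log-likelihood matches brute-force summation", {
  tab <- rand_table(6, L = 3, A = 3, seed = 31)
  K <- 2
  set.seed(31)
  Q <- matrix(rgamma(6 * K, 1), 6); Q <- Q / rowSums(Q)
  P <- lapply(1:3, function(l) {
    m <- matrix(rgamma(K * 3, 1), K); m <- m / rowSums(m)
    colnames(m) <- as.character(1:3)
    m
  })
  brute <- 0
  for (i in 1:6) for (l in 1:3) for (al in c(tab$a1[i, l], tab$a2[i, l]))
    brute <- brute + log(sum(Q[i, ] * P[[l]][, al]))
  expect_equal(admixture_loglik(Q, P, tab), brute)
})

test_that("one-hot memberships with matching fixed alleles give logL 0", {
  tab <- mk_table(matrix(c(1L, 2L), 2, 2), matrix(c(1L, 2L), 2, 2))
  Q <- diag(2)
  P <- lapply(1:2, function(l) {
    m <- rbind(c(1, 0), c(0, 1))
    colnames(m) <- c("1", "2")
    m
  })
  expect_equal(admixture_loglik(Q, P, tab), 0)
})

test_that("K = 1 collapses to pooled frequencies in one iteration", {
  tab <- rand_table(20, L = 3, A = 4, seed = 32)
  res <- fit_admixture_em(tab, K = 1, n_runs = 1, seed = 1)[[1]]
  expect_equal(res$iterations, 1L)
  expect_true(all(res$Q == 1))
  pooled <- allele_counts(tab)
  for (l in 1:3) {
    p <- pooled[[l]] / sum(pooled[[l]])
    expect_equal(as.numeric(res$P[[l]]), as.numeric(p), tolerance = 1e-4)
  }
})

test_that("EM log-likelihood is non-decreasing and beats K = 1", {
  tab <- rand_table(40, L = 4, A = 4, seed = 33)
  r1 <- fit_admixture_em(tab, 1, n_runs = 1, seed = 5)[[1]]
  # unstructured random data may legitimately hit the iteration cap
  r2 <- suppressWarnings(fit_admixture_em(tab, 2, n_runs = 4, seed = 5))[[1]]
  r3 <- suppressWarnings(fit_admixture_em(tab, 3, n_runs = 4, seed = 5))[[1]]
  expect_gte(r2$loglik, r1$loglik - 1e-6)
  expect_gte(r3$loglik, r1$loglik - 1e-6)
  # rows of Q are proper membership vectors
  expect_equal(rowSums(r2$Q), rep(1, 40), tolerance = 1e-9)
  expect_true(all(r2$Q >= 0))
  # P rows are proper frequency vectors
  for (l in seq_along(r2$P))
    expect_equal(rowSums(r2$P[[l]]), rep(1, 2), tolerance = 1e-9)
})

test_that("relabeling clusters permutes Q without changing the likelihood", {
  tab <- rand_table(25, L = 3, A = 4, seed = 34)
  res <- fit_admixture_em(tab, 2, n_runs = 2, seed = 7)[[1]]
  swapQ <- res$Q[, 2:1]
  swapP <- lapply(res$P, function(m) m[2:1, , drop = FALSE])
  expect_equal(admixture_loglik(swapQ, swapP, tab), res$loglik,
               tolerance = 1e-9)
})

test_that("Evanno delta-K reproduces the closed-form example", {
  # mean L = (-100, -50, -45); K = 2 runs (-50.5, -50, -49.5), sd = 0.5:
  # deltaK(2) = |(-45 + 50) - (-50 + 100)| / 0.5 = 90
  ll <- cbind(`1` = rep(-100, 3),
              `2` = c(-50.5, -50, -49.5),
              `3` = rep(-45, 3))
  dk <- suppressWarnings(evanno_delta_k(ll, 1:3))
  expect_equal(dk$delta_k[2], 90)
  expect_true(is.na(dk$delta_k[1]) && is.na(dk$delta_k[3]))
  expect_equal(attr(dk, "best_k"), 2L)
})

test_that("linear mean log-likelihood gives zero delta-K in the interior", {
  set.seed(35)
  ll <- rbind(c(-300, -200, -100, 0), c(-300, -200, -100, 0) + 0.3,
              c(-300, -200, -100, 0) - 0.3)
  colnames(ll) <- 1:4
  dk <- evanno_delta_k(ll)
  expect_equal(dk$delta_k[2:3], c(0, 0))
})

test_that("two disjoint gene pools are recovered at K = 2", {
  sim <- simulate_landscape(landscape_config(
    n_trees = 240, extent = c(-79, -71, -14, -4), ancestral = "disjoint",
    cline_scale = 0.3, clonal_patch = NULL, hotspot = NULL,
    withhold_hotspot = FALSE, inbreeding_region = NULL, seed = 36))
  scan <- suppressWarnings(admixture_scan(sim$table, 1:3, n_runs = 4,
                                          seed = 36, max_iter = 80))
  dk <- suppressWarnings(evanno_delta_k(scan$loglik, 1:3))
  expect_equal(attr(dk, "best_k"), 2L)
  best <- scan$best[[2]]
  pred <- apply(best$Q, 1, which.max)
  truthlab <- ifelse(sim$truth$q_true > 0.5, 1, 2)
  acc <- max(mean(pred == truthlab), mean(pred == 3 - truthlab))
  expect_gt(acc, 0.95)
})

test_that("cluster-probability maps average Q and sum to one per cell", {
  tab <- rand_table(30, L = 2, A = 3, seed = 37)
  grid <- make_grid(c(-80, -77, -6, -3))
  asn <- resample_trees(tab, grid, neighborhood_mask())
  Q <- cbind(rep(c(1, 0), length.out = 30), rep(c(0, 1), length.out = 30))
  rA <- map_cluster_probability(asn, Q, 1, min_n = 1)
  rB <- map_cluster_probability(asn, Q, 2, min_n = 1)
  ok <- !is.na(rA$values)
  expect_equal(rA$values[ok] + rB$values[ok], rep(1, sum(ok)))
  # homogeneous memberships map to the constant
  Q1 <- cbind(rep(1, 30), rep(0, 30))
  r1 <- map_cluster_probability(asn, Q1, 1, min_n = 1)
  expect_true(all(r1$values[!is.na(r1$values)] == 1))
  # the min_n threshold blanks small cells
  r20 <- map_cluster_probability(asn, Q, 1, min_n = 20)
  cnt <- cell_counts(asn)
  expect_true(all(is.na(r20$values[which(cnt$values < 20)])))
})
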