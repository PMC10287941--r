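test_that("ARI is 1 for identical or relabelled partitions and near 0 for random ones", {
  a <- rep(c("x", "y", "z"), times = c(10, 20, 30))
  names(a) <- sprintf("i%02d", seq_along(a))
  expect_equal(adjusted_rand_index(a, a), 1)
  relab <- c(x = "3", y = "1", z = "2")[a]
  names(relab) <- names(a)
  expect_equal(adjusted_rand_index(a, relab), 1)
  expect_equal(adjusted_rand_index(a, relab), adjusted_rand_index(relab, a))
  set.seed(31)
  aris <- replicate(50, {
    p <- sample(5, 1000, replace = TRUE)
    q <- sample(5, 1000, replace = TRUE)
    adjusted_rand_index(p, q)
  })
  expect_lt(max(abs(aris)), 0.05)
  b <- a; names(b) <- paste0("other", seq_along(b))
  expect_error(adjusted_rand_index(a, b), "item set|share no items")
})

test_that("gene removal keeps ARI at 1 while no anchor is touched and flags total removal", {
  expr <- matrix(c(9, 1, 0,  9, 1, 0,  0, 1, 9,  0, 1, 9), 3, 4,
                 dimnames = list(c("A", "mid", "B"), sprintf("c%d", 1:4)))
  pr <- toy_priority(c(A = 0.9, mid = 0.5, B = 0.8))
  # removing one gene per step: 3 steps; "mid" is never an anchor
  curve <- gene_removal_experiment(expr, pr, "bottom_up", step = 1, seed = 0)
  expect_equal(curve$ari[1], 1)          # first removed gene is "mid" (lowest rts)
  expect_true(curve$undefined[3])
  expect_equal(curve$ari[3], 0)
  expect_error(gene_removal_experiment(expr, pr, "sideways"), "arg")
})

test_that("spearman correlation of peak profiles matches rank arithmetic", {
  prof <- cbind(p1 = c(1, 2, 3, 4, 5), p2 = c(2, 4, 6, 8, 10),
                p3 = c(5, 4, 3, 2, 1))
  rownames(prof) <- sprintf("g%d", 1:5)
  rho <- spearman_peak_correlation(prof)
  expect_equal(rho["p1", "p2"], 1)
  expect_equal(rho["p1", "p3"], -1)
  expect_equal(rho, t(rho))
  expect_true(all(diag(rho) == 1))
  prof2 <- cbind(prof, flat = rep(3, 5))
  expect_warning(rho2 <- spearman_peak_correlation(prof2), "constant")
  expect_true(is.na(rho2["p1", "flat"]))
  expect_error(spearman_peak_correlation(prof[, 1, drop = FALSE]), ">= 2")
})

test_that("hvg selection surfaces planted excess variance at matched mean", {
  set.seed(32)
  n_cells <- 200
  expr <- matrix(rpois(300 * n_cells, 10), 300, n_cells,
                 dimnames = list(sprintf("g%03d", 1:300), sprintf("c%03d", 1:n_cells)))
  # planted: same mean 10, variance ~10x (mixture of 0 and 20)
  expr["g001", ] <- sample(c(0, 20), n_cells, replace = TRUE)
  hv <- select_hvg(expr, n = 10)
  expect_equal(hv[1], "g001")
  expect_equal(sort(select_hvg(expr, n = 300)), sort(rownames(expr)))
  expect_error(select_hvg(expr, n = 301), "exceeds")
})

test_that("rank-bin enrichment reproduces the 2x2 odds ratio and hypergeometric tail", {
  # bin 1 of 10: 100 of 1000 genes, 10 of 110 targets inside
  ranking <- sprintf("g%04d", 1:1000)
  target <- c(sprintf("g%04d", 1:10), sprintf("g%04d", 501:600))
  res <- rank_bin_enrichment(ranking, target, n_bins = 10)
  expect_equal(res$n_target[1], 10)
  expect_equal(res$odds_ratio[1], (10 * (1000 - 100 - 100)) / (90 * 100))
  expect_equal(res$p[1], oracle_hyper_upper(10, 110, 1000, 100))
  # cross-check the one-tailed p against fisher.test on the same table
  ft <- fisher.test(matrix(c(10, 90, 100, 800), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(res$p[1], ft$p.value)
  expect_error(rank_bin_enrichment(ranking, "absent"), "subset")
})

test_that("rank-bin enrichment tails behave at the extremes", {
  ranking <- sprintf("g%03d", 1:200)
  # all targets in bin 1 -> minimal tail there, depleted elsewhere
  res <- rank_bin_enrichment(ranking, sprintf("g%03d", 1:20), n_bins = 10)
  expect_equal(res$p[1], oracle_hyper_upper(20, 20, 200, 20))
  expect_true(all(res$p[-1] == 1))
  # uniformly spread target -> odds ratios hover near 1
  unif <- sprintf("g%03d", seq(5, 200, by = 10))
  res2 <- rank_bin_enrichment(ranking, unif, n_bins = 10)
  expect_true(all(res2$n_target == 2))
  expect_lt(max(abs(res2$odds_ratio - 1)), 0.35)
})
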