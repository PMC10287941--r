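test_that("breadth PCA recovers planted low-rank structure", {
  set.seed(21)
  # rank-1: every gene is a scalar multiple of one sample pattern
  pattern <- runif(8, 0.5, 2)
  scal <- runif(120, 0, 1000)
  B1 <- outer(scal, pattern)
  dimnames(B1) <- list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:8))
  p1 <- fit_h3k27me3_pca(B1, 1)
  expect_gte(p1$explained[1], 0.999)
  # a rank-1 matrix cannot support more components
  expect_error(fit_h3k27me3_pca(B1, 3), "rank")
  # duplicated samples load identically (full-rank noise background)
  Bn <- B1 + matrix(runif(960, 0, 50), 120, 8)
  B2 <- cbind(Bn, dup = Bn[, 1])
  p2 <- fit_h3k27me3_pca(B2, 4)
  expect_equal(p2$loadings["s01", ], p2$loadings["dup", ],
               ignore_attr = TRUE)
  expect_true(all(diff(p2$explained) <= 1e-12))
})

test_that("two planted orthogonal deposition programs land on the first two PCs", {
  set.seed(22)
  n_s <- 10
  prog1 <- c(rep(1, 5), rep(0, 5))          # first half of samples
  prog2 <- c(rep(0, 5), rep(1, 5))          # second half
  B <- rbind(outer(runif(60, 500, 1500), prog1),
             outer(runif(60, 500, 1500), prog2)) +
       matrix(rnorm(1200, 0, 5), 120, n_s)
  dimnames(B) <- list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:n_s))
  p <- fit_h3k27me3_pca(B, 4)
  cos_sim <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  # each planted direction is captured by one of the top two loadings
  contrast <- prog1 - prog2                  # centred program axis
  expect_gt(max(cos_sim(p$loadings[, 1], contrast),
                cos_sim(p$loadings[, 2], contrast)), 0.95)
})

test_that("permutation p-values follow (r + 1) / (n_perm + 1) with exact extremes", {
  # deterministic scores: one clear top gene, one clear bottom gene
  scores <- matrix(c(100, seq(0.01, 0.99, length.out = 99), -100), ncol = 1,
                   dimnames = list(c("top", sprintf("m%02d", 1:99), "bottom"), "PC1"))
  pcm <- structure(list(scores = scores), class = "pc_model")
  res <- pattern_enrichment(pcm, c("top", "bottom"), n_perm = 1000, seed = 1,
                            stat = "max")
  expect_equal(res$p[res$gene_id == "top"], 1 / 1001)     # beats all draws
  expect_equal(res$p[res$gene_id == "bottom"], 1)          # beaten by all
  expect_true(all(res$p >= 1 / 1001 & res$p <= 1))
  expect_true(res$strong[res$gene_id == "top"])
  expect_false(res$strong[res$gene_id == "bottom"])
  # p is consistent with the reported exceedance count r for every gene
  expect_equal(res$p, (res$r + 1) / (1000 + 1))
  expect_error(pattern_enrichment(pcm, "absent"), "not in universe")
})

test_that("permutation enrichment is deterministic under a fixed seed", {
  set.seed(23)
  scores <- matrix(rnorm(200), 100, 2,
                   dimnames = list(sprintf("g%03d", 1:100), c("PC1", "PC2")))
  pcm <- structure(list(scores = scores), class = "pc_model")
  gs <- sprintf("g%03d", 1:10)
  r1 <- pattern_enrichment(pcm, gs, n_perm = 200, seed = 7)
  r2 <- pattern_enrichment(pcm, gs, n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  r3 <- pattern_enrichment(pcm, gs, n_perm = 200, seed = 8)
  expect_false(identical(r1$r, r3$r))
})

test_that("PCs are ranked by gene-set variance", {
  set.seed(24)
  scores <- matrix(rnorm(300, sd = 0.1), 100, 3,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("PC", 1:3)))
  gs <- sprintf("g%03d", 1:20)
  scores[gs, 3] <- seq(-5, 5, length.out = 20)   # set spreads along PC3 only
  scores[, 2] <- 0                               # constant -> ranked last
  pcm <- structure(list(scores = scores), class = "pc_model")
  sel <- rank_pcs_by_gene_set_variance(pcm, gs, m = 3)
  expect_equal(sel[1], 3L, ignore_attr = TRUE)
  expect_equal(sel[3], 2L, ignore_attr = TRUE)
  expect_equal(sort(as.integer(sel)), 1:3)       # m = all -> identity set
  expect_error(rank_pcs_by_gene_set_variance(pcm, "g001"), ">= 2")
  expect_error(rank_pcs_by_gene_set_variance(pcm, gs, m = 9), "exceeds")
})

test_that("the full parser recovers planted deposition programs", {
  bp <- simulate_breadth_programs(seed = 0)
  gl <- names(bp$program)[bp$program > 0]
  pr <- triage_parser(gl, bp$breadth, n_pcs = 10, m = 10, theta_max = 8,
                      repeats = 10, seed = 42, n_perm = 100)
  expect_equal(pr$scan$theta_star, 3L)
  tab <- table(pr$clusters$cluster, bp$program[gl])
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(purity, 0.9)
  expect_true(all(abs(rowSums(pr$model$posterior) - 1) < 1e-9))
  expect_error(triage_parser(c(gl, "ghost"), bp$breadth), "absent")
})
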