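test_that("cell weights take the rts of the highest-expressed priority gene", {
  expr <- matrix(c(5, 2,   0, 0,   5, 5), 2, 3,
                 dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
  pr <- toy_priority(c(A = 0.3, B = 0.9))
  w <- assign_cell_weights(expr, pr)
  expect_equal(w["c1", "weight"], 0.3)            # max expression wins
  expect_equal(w["c1", "anchor_candidate"], "A")
  expect_equal(w["c2", "weight"], 0)              # nothing expressed
  expect_true(is.na(w["c2", "anchor_candidate"]))
  expect_equal(w["c3", "weight"], 0.9)            # tie -> higher rts
  expect_error(assign_cell_weights(expr, toy_priority(setNames(numeric(0), character(0)))),
               "empty")
})

make_blobs <- function(centres, n_per, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i)
    cbind(rnorm(n_per, centres[i, 1], sd), rnorm(n_per, centres[i, 2], sd))))
  rownames(x) <- sprintf("c%04d", seq_len(nrow(x)))
  x
}

test_that("superlevel sets are nested and thresholds strictly increase", {
  emb <- make_blobs(rbind(c(0, 0), c(6, 0)), 80)
  den <- weighted_kde(emb, rep(1, nrow(emb)), h = 0.5)
  lv <- superlevel_clusters(den, emb)
  expect_true(all(diff(lv$thresholds) > 0))
  for (k in seq_len(length(lv$levels) - 1)) {
    expect_true(all(lv$levels[[k + 1]]$cells %in% lv$levels[[k]]$cells))
  }
})

test_that("a single blob yields one peak containing the density mode", {
  emb <- make_blobs(matrix(c(0, 0), 1), 300, sd = 0.6, seed = 2)
  den <- weighted_kde(emb, rep(1, 300), h = 0.4)
  lv <- suppressWarnings(superlevel_clusters(den, emb))
  pk <- select_peaks(lv)
  expect_equal(nrow(attr(pk, "peaks")), 1L)
  mode_cell <- names(which.max(den$cell_density))
  expect_true(mode_cell %in% pk$cell)
})

test_that("two separated blobs yield two peaks matching blob labels", {
  emb <- make_blobs(rbind(c(0, 0), c(8, 0)), 200, sd = 0.6, seed = 3)
  truth <- rep(c("L", "R"), each = 200)
  names(truth) <- rownames(emb)
  den <- weighted_kde(emb, rep(1, 400), h = 0.4)
  lv <- suppressWarnings(superlevel_clusters(den, emb))
  pk <- select_peaks(lv)
  expect_equal(nrow(attr(pk, "peaks")), 2L)
  mem <- setNames(pk$peak_id, pk$cell)
  expect_gt(adjusted_rand_index(truth[names(mem)], mem), 0.95)
})

test_that("peak calls are invariant to positive rescaling of the density field", {
  emb <- make_blobs(rbind(c(0, 0), c(8, 0)), 150, sd = 0.6, seed = 4)
  den <- weighted_kde(emb, rep(1, 300), h = 0.4)
  pk1 <- select_peaks(suppressWarnings(superlevel_clusters(den, emb)))
  den2 <- den
  den2$cell_density <- den$cell_density * 1234.5
  pk2 <- select_peaks(suppressWarnings(superlevel_clusters(den2, emb)))
  expect_equal(as.data.frame(pk1), as.data.frame(pk2))
})

test_that("with equal weights the peaks match the unweighted density modes", {
  emb <- make_blobs(rbind(c(0, 0), c(9, 0)), 150, sd = 0.6, seed = 5)
  h <- 0.4
  den <- weighted_kde(emb, rep(2.5, 300), h = h)
  # independent oracle: unweighted KDE mode per blob
  dens_oracle <- oracle_kde(emb, emb, h)
  expect_lt(max(abs(den$cell_density - dens_oracle)), 1e-9)
  pk <- select_peaks(suppressWarnings(superlevel_clusters(den, emb)))
  summ <- attr(pk, "peaks")
  expect_equal(nrow(summ), 2L)
  # each peak contains its side's oracle mode
  left_mode <- rownames(emb)[which.max(dens_oracle[1:150])]
  right_mode <- rownames(emb)[150 + which.max(dens_oracle[151:300])]
  expect_true(all(c(left_mode, right_mode) %in% pk$cell))
  expect_false(pk$peak_id[pk$cell == left_mode] == pk$peak_id[pk$cell == right_mode])
})

test_that("clusters below the size floor are not peaks", {
  emb <- make_blobs(rbind(c(0, 0), c(8, 0)), c(200), sd = 0.5, seed = 6)
  # second blob of only 8 cells
  emb <- rbind(make_blobs(matrix(c(0, 0), 1), 200, sd = 0.5, seed = 6),
               make_blobs(matrix(c(8, 0), 1), 8, sd = 0.2, seed = 7))
  rownames(emb) <- sprintf("c%04d", seq_len(nrow(emb)))
  den <- weighted_kde(emb, rep(1, nrow(emb)), h = 0.4)
  pk <- select_peaks(suppressWarnings(superlevel_clusters(den, emb)), min_cells = 20)
  expect_equal(nrow(attr(pk, "peaks")), 1L)
  expect_false(any(tail(rownames(emb), 8) %in% pk$cell))
})

test_that("anchor genes follow mean expression with rts tie-break", {
  expr <- matrix(c(4, 4, 0,   4, 4, 0,   0, 0, 9), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("c1", "c2", "c3")))
  pr <- toy_priority(c(A = 0.2, B = 0.4, C = 0.8))
  expect_equal(anchor_gene(c("c1", "c2"), expr, pr), "B")   # tie -> higher rts
  expect_equal(anchor_gene("c3", expr, pr), "C")
  expr0 <- matrix(0, 3, 1, dimnames = list(c("A", "B", "C"), "c1"))
  expect_warning(a <- anchor_gene("c1", expr0, pr), "no priority gene")
  expect_true(is.na(a))
})

test_that("jaccard similarity matches set arithmetic", {
  l <- list(p = sprintf("g%03d", 1:100), q = sprintf("g%03d", 1:100),
            r = sprintf("h%03d", 1:100), s = sprintf("g%03d", 51:150))
  J <- jaccard_similarity(l)
  expect_equal(J["p", "q"], 1)
  expect_equal(J["p", "r"], 0)
  expect_equal(J["p", "s"], 50 / 150)
  expect_equal(J, t(J))
  expect_true(all(diag(J) == 1))
  expect_error(jaccard_similarity(list(a = character(0), b = "g1")), "empty")
})

test_that("the peak dendrogram joins identical peaks first and splits planted families", {
  l <- list(p1 = sprintf("g%03d", 1:100), p2 = sprintf("g%03d", 1:100),
            p3 = sprintf("h%03d", 1:100))
  hc <- peak_dendrogram(jaccard_similarity(l))
  expect_equal(hc$height[1], 0)                       # identical pair merges at 0
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("p1", "p2"))
  # block structure: two families of similar peaks separate at the top split
  fam <- list(a1 = sprintf("g%03d", 1:100), a2 = sprintf("g%03d", 3:102),
              b1 = sprintf("h%03d", 1:100), b2 = sprintf("h%03d", 3:102))
  hc2 <- peak_dendrogram(jaccard_similarity(fam))
  top <- cutree(hc2, k = 2)
  expect_equal(unname(top[c("a1", "a2")]), rep(top[["a1"]], 2))
  expect_equal(unname(top[c("b1", "b2")]), rep(top[["b1"]], 2))
  expect_false(top[["a1"]] == top[["b1"]])
  Jn <- jaccard_similarity(l); Jn[1, 2] <- NaN; Jn[2, 1] <- NaN
  expect_error(peak_dendrogram(Jn), "NaN")
})

test_that("end-to-end clustering recovers planted atlas structure", {
  a <- simulate_atlas(seed = 1)
  epi <- simulate_epigenome(seed = 1)
  r <- compute_rts(compute_gene_breadth(epi$intervals, epi$gene_models))
  cl <- suppressWarnings(triage_cluster(normalize_library_size(a$counts),
                                        a$embedding, r, bandwidth = 0.3))
  summ <- attr(cl$peaks, "peaks")
  expect_equal(nrow(summ), 3L)
  ari <- adjusted_rand_index(a$labels[names(cl$membership)], cl$membership)
  expect_gt(ari, 0.9)
  # anchors are markers of the matching planted type
  for (i in seq_len(nrow(summ))) {
    cells <- cl$peaks$cell[cl$peaks$peak_id == summ$peak_id[i]]
    type <- names(which.max(table(a$labels[cells])))
    expect_true(summ$anchor_gene[i] %in% a$marker_map[[type]])
  }
})
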