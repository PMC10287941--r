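gm2 <- function(tss) {
  ids <- sprintf("g%d", seq_along(tss))
  structure(data.frame(gene_id = ids, chrom = rep("chrS", length(ids)),
                       strand = rep("+", length(ids)),
                       tss = as.integer(tss), row.names = ids,
                       stringsAsFactors = FALSE),
            class = c("gene_models", "data.frame"))
}
iv1 <- function(starts, ends) {
  structure(list(s1 = GenomicRanges::GRanges("chrS",
    IRanges::IRanges(start = starts + 1L, end = ends))),
    class = c("interval_sets", "list"))
}

test_that("breadth is the broadest (or summed) overlapping interval in the TSS window", {
  # one interval [1000,6000), tss 3000, w 2500 -> 5000
  b <- compute_gene_breadth(iv1(1000L, 6000L), gm2(3000), 2500)
  expect_equal(unname(b["g1", "s1"]), 5000L)
  # two overlapping intervals 2000 and 3000 bp
  iv <- iv1(c(2000L, 2500L), c(4000L, 5500L))
  expect_equal(unname(compute_gene_breadth(iv, gm2(3000))["g1", "s1"]), 3000L)
  expect_equal(unname(compute_gene_breadth(iv, gm2(3000), mode = "total")["g1", "s1"]),
               5000L)
  # no interval within the window -> 0
  expect_equal(unname(compute_gene_breadth(iv1(100000L, 101000L), gm2(3000))["g1", "s1"]),
               0L)
  # window is half-open: interval starting exactly at tss + w + 1 misses
  expect_equal(unname(compute_gene_breadth(iv1(5501L, 6000L), gm2(3000))["g1", "s1"]),
               0L)
  expect_equal(unname(compute_gene_breadth(iv1(5500L, 6000L), gm2(3000))["g1", "s1"]),
               500L)
})

test_that("breadth computation rejects empty gene sets and flags chrom mismatch", {
  expect_error(compute_gene_breadth(iv1(0L, 10L), gm2(integer(0))), "empty gene set")
  iv <- structure(list(s1 = GenomicRanges::GRanges("chrOther",
          IRanges::IRanges(1, 100))), class = c("interval_sets", "list"))
  expect_warning(b <- compute_gene_breadth(iv, gm2(50)), "chromosome")
  expect_true(all(b == 0))
})

test_that("rts follows a * v with inclusive top-fraction ties", {
  # 20 nonzero genes per sample -> ceiling(0.05 * 20) = 1 top slot
  B <- matrix(0L, 20, 3, dimnames = list(c("A", sprintf("f%02d", 1:19)),
                                         c("s1", "s2", "s3")))
  B[2:20, ] <- 100L           # fillers: nonzero everywhere
  B["f01", ] <- 4600L         # top gene of s2 and s3; max breadth_sum
  B["A", "s1"] <- 5000L       # top of s1 -> one flag for A
  B["A", "s2"] <- 1900L
  # breadth_sum: A = 6900, f01 = 13800 = max -> a(A) = 0.5, v(A) = 1/3
  r <- compute_rts(B, top_fraction = 0.05)
  expect_equal(r["A", "v"], 1 / 3)
  expect_equal(r["A", "a"], 0.5)
  expect_equal(r["A", "rts"], 0.5 * (1 / 3))
  # f01 is displaced from s1's single top slot by A -> v = 2/3, a = 1
  expect_equal(r["f01", "rts"], 2 / 3)
  expect_true(all(r$rts >= 0 & r$rts <= 1))
  # a gene topping every sample with the maximal breadth_sum scores exactly 1
  B2 <- B; B2["A", ] <- 0L; B2["f01", ] <- 5000L
  expect_equal(compute_rts(B2)["f01", "rts"], 1)
  # never-flagged fillers have rts 0 regardless of breadth
  expect_equal(unname(r["f05", "rts"]), 0)
})

test_that("rts is scale-invariant and monotone in breadth", {
  set.seed(7)
  B <- matrix(rpois(300, 800), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:5)))
  r1 <- compute_rts(B)
  r2 <- compute_rts(B * 17L)
  expect_equal(r1$rts, r2$rts)
  expect_equal(r1$v, r2$v)
  expect_equal(r1$a, r2$a)
  # raising one gene's breadth in one sample never lowers its rts
  g <- "g10"
  for (delta in c(50L, 5000L)) {
    B2 <- B; B2[g, 2] <- B2[g, 2] + delta
    expect_gte(compute_rts(B2)[g, "rts"], r1[g, "rts"])
  }
})

test_that("degenerate rts inputs error clearly", {
  B <- matrix(0L, 5, 3, dimnames = list(letters[1:5], c("s1", "s2", "s3")))
  expect_error(compute_rts(B), "no H3K27me3 signal")
  expect_error(compute_rts(matrix(1L, 5, 1)), "2 samples")
  expect_error(compute_rts(matrix(1L, 5, 3), top_fraction = 1.5), "top_fraction")
})

test_that("planted broad-domain genes occupy the top rts ranks", {
  epi <- simulate_epigenome(seed = 3)
  b <- compute_gene_breadth(epi$intervals, epi$gene_models)
  r <- compute_rts(b)
  expect_setequal(head(r$gene_id, 50), epi$truth$regulatory_genes)
})

test_that("fixed-threshold priority selection matches the stated examples", {
  tab <- toy_rts_table(c(A = 0.5, B = 0.02, C = 0.001))
  pr <- select_priority_genes(tab, method = "fixed", fixed_threshold = 0.013)
  expect_equal(unclass(pr)[1:2], c("A", "B"))
  expect_length(pr, 2L)
  expect_warning(pr0 <- select_priority_genes(tab, "fixed", fixed_threshold = 1),
                 "no gene")
  expect_length(pr0, 0L)
})

test_that("knee detection finds a planted two-regime change point", {
  set.seed(11)
  rts <- c(0.5 * exp(-(0:99) / 60), runif(900, 0, 0.002))
  names(rts) <- sprintf("g%04d", seq_along(rts))
  pr <- select_priority_genes(toy_rts_table(rts))
  expect_gte(length(pr), 90L)
  expect_lte(length(pr), 110L)
  # the knee sits within +/- 10 ranks of the planted change point
  expect_lte(abs(attr(pr, "knee_rank") - 100), 10)
  # nearly all selected genes come from the planted head
  idx <- as.integer(sub("^g", "", unclass(pr)))
  expect_gte(mean(idx <= 100), 0.9)
})

test_that("flat rts curves are rejected for knee detection", {
  rts <- setNames(rep(0.4, 150), sprintf("g%03d", 1:150))
  expect_error(select_priority_genes(toy_rts_table(rts)), "flat|knee")
})
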