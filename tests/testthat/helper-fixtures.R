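# Shared helpers: tiny hand-built objects and independent oracles.

# rts_table from a named rts vector (breadth columns filled consistently)
toy_rts_table <- function(rts) {
  ord <- order(-rts, names(rts))
  structure(data.frame(gene_id = names(rts)[ord],
                       breadth_sum = rts[ord], a = rts[ord],
                       v = as.numeric(rts[ord] > 0), rts = rts[ord],
                       row.names = names(rts)[ord], stringsAsFactors = FALSE),
            top_fraction = 0.05, class = c("rts_table", "data.frame"))
}

toy_priority <- function(rts) {
  structure(names(sort(rts, decreasing = TRUE)), threshold = 0,
            method = "fixed", rts = rts, class = "priority_genes")
}

# independent unweighted KDE oracle: direct double sum via dnorm products
oracle_kde <- function(query, cells, h) {
  vapply(seq_len(nrow(query)), function(i) {
    mean(dnorm(query[i, 1], cells[, 1], h) * dnorm(query[i, 2], cells[, 2], h))
  }, 0)
}

# exhaustive hypergeometric upper tail: P(X >= k) by direct summation
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# one-line BED writer
write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}
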