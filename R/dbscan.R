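## Exact DBSCAN over 2D points. Written in-package: no density-based spatial
## clustering routine ships with the installed stack, and the algorithm is a
## short fixed-radius neighbour expansion.

#' Density-based spatial clustering (DBSCAN)
#'
#' Standard DBSCAN: points with at least `min_samples` neighbours within
#' `eps` (counting themselves) are core points; clusters are the connected
#' components of core points under eps-reachability, plus border points
#' attached to the first core cluster that reaches them. Non-reached points
#' are noise (label 0). Deterministic: expansion follows row order.
#'
#' @param x n x d coordinate matrix.
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbourhood size for a core point.
#' @return integer vector of cluster labels (0 = noise).
#' @export
dbscan_cluster <- function(x, eps, min_samples = 5L) {
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  nb <- .radius_neighbours(x, eps)
  core <- lengths(nb) >= min_samples
  labels <- integer(n)                 # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# neighbour lists within radius eps (self included), blockwise distances
.radius_neighbours <- function(x, eps, block = 1024L) {
  n <- nrow(x)
  out <- vector("list", n)
  eps2 <- eps^2
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(x[s:e, 1], x[, 1], `-`)^2 + outer(x[s:e, 2], x[, 2], `-`)^2
    for (k in seq_len(e - s + 1L))
      out[[s + k - 1L]] <- which(d2[k, ] <= eps2)
  }
  out
}

#' Median nearest-neighbour distance of a point set
#'
#' Used for the default DBSCAN radius (3x this value).
#'
#' @param x n x 2 coordinate matrix.
#' @param block rows per distance block (memory/speed trade-off).
#' @return median over points of the distance to the nearest other point.
#' @export
median_nn_distance <- function(x, block = 1024L) {
  n <- nrow(x)
  if (n < 2L) .stop2("need >= 2 points")
  nn <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(x[s:e, 1], x[, 1], `-`)^2 + outer(x[s:e, 2], x[, 2], `-`)^2
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    nn[s:e] <- sqrt(apply(d2, 1, min))
  }
  stats::median(nn)
}
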