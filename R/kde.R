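## Weighted Gaussian kernel density estimation in 2D. The bandwidth rule is
## Scott's rule with its leading constant tightened to 0.3 for scRNA-seq
## embeddings: h = 0.3 * n^(-1/(d+4)).

#' Embedding bandwidth for the weighted KDE
#'
#' `h = 0.3 * n^(-1/(d+4))` - Scott's rule with the constant adjusted for
#' single-cell 2D embeddings.
#'
#' @param n number of cells (>= 1).
#' @param d embedding dimensionality (default 2).
#' @return bandwidth h.
#' @examples
#' kde_bandwidth(1)   # 0.3
#' kde_bandwidth(64)  # 0.15
#' @export
kde_bandwidth <- function(n, d = 2) {
  if (n < 1) .stop2("n must be >= 1")
  0.3 * n^(-1 / (d + 4))
}

#' RTS-weighted Gaussian kernel density estimate over a 2D embedding
#'
#' Density at x is `sum_i w_i/(sum w) * (2*pi*h^2)^-1 *
#' exp(-||x - x_i||^2 / (2 h^2))`: an isotropic bivariate Gaussian kernel of
#' scale h at every cell, mixed with normalised per-cell weights, so the
#' field integrates to 1. Cells with weight 0 contribute nothing but still
#' receive a density value at their own coordinates.
#'
#' @param embedding cells x 2 coordinate matrix (rownames = cell ids).
#' @param weights per-cell non-negative weights, named or in row order
#'   (a `cell_weights` object from [assign_cell_weights()] also works).
#' @param h bandwidth; default [kde_bandwidth()] of the cell count.
#' @param grid_n if > 0, also evaluate the density on a `grid_n x grid_n`
#'   raster spanning the embedding (for plotting / quadrature).
#' @return list with `h`, `n`, `cell_density` (named per-cell density),
#'   `weights` (normalised), and optionally `grid` (`x`, `y`, `z`);
#'   class `"density_model"`.
#' @export
weighted_kde <- function(embedding, weights, h = NULL, grid_n = 0) {
  if (is.list(weights) && !is.null(weights$weight)) weights <- weights$weight
  n <- nrow(embedding)
  if (!is.null(names(weights))) weights <- weights[rownames(embedding)]
  if (length(weights) != n) .stop2("weights length must match cell count")
  if (any(weights < 0)) .stop2("negative weights")
  sw <- sum(weights)
  if (sw <= 0) .stop2("no priority signal: all cell weights are zero")
  if (is.null(h)) h <- kde_bandwidth(n, 2)
  if (h <= 0) .stop2("bandwidth must be positive")
  wn <- weights / sw
  cell_density <- .kde_eval(embedding, embedding, wn, h)
  names(cell_density) <- rownames(embedding)
  out <- list(h = h, n = n, d = 2L, cell_density = cell_density, weights = wn)
  if (grid_n > 0) {
    pad <- 4 * h
    gx <- seq(min(embedding[, 1]) - pad, max(embedding[, 1]) + pad, length.out = grid_n)
    gy <- seq(min(embedding[, 2]) - pad, max(embedding[, 2]) + pad, length.out = grid_n)
    pts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
    z <- .kde_eval(pts, embedding, wn, h)
    out$grid <- list(x = gx, y = gy,
                     z = matrix(z, nrow = grid_n, ncol = grid_n))
  }
  structure(out, class = "density_model")
}

# density of the weighted KDE at arbitrary query points; blockwise to keep
# the n_query x n_cell kernel matrix small
.kde_eval <- function(query, cells, wn, h, block = 2048L) {
  nq <- nrow(query)
  norm <- 1 / (2 * pi * h^2)
  out <- numeric(nq)
  idx <- which(wn > 0)
  cx <- cells[idx, 1]; cy <- cells[idx, 2]; w <- wn[idx]
  for (s in seq(1L, nq, by = block)) {
    e <- min(s + block - 1L, nq)
    d2 <- outer(query[s:e, 1], cx, `-`)^2 + outer(query[s:e, 2], cy, `-`)^2
    out[s:e] <- as.numeric(exp(-d2 / (2 * h^2)) %*% w) * norm
  }
  out
}

#' Evaluate a fitted density model at new points
#'
#' @param model a `density_model`.
#' @param points m x 2 matrix of query coordinates.
#' @param embedding the cells x 2 matrix the model was fit on.
#' @return numeric density values.
#' @export
kde_evaluate <- function(model, points, embedding) {
  .kde_eval(points, embedding, model$weights, model$h)
}
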