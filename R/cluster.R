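## Peak calling on a 2D embedding: per-cell RTS weights, weighted KDE,
## superlevel-set DBSCAN decomposition at 10 contour levels, selection of
## innermost clusters as peaks, anchor genes, and the Jaccard dendrogram
## over per-peak DS rankings.

#' Per-cell weights from the highest-expressed priority gene
#'
#' Each cell is weighted by the RTS of its highest-expressed priority gene
#' (ties by expression resolve to the higher RTS, then lexicographic gene
#' id). Cells expressing no priority gene get weight 0 and no anchor
#' candidate.
#'
#' @param expr genes x cells normalised matrix.
#' @param priority a `priority_genes` object (carries per-gene RTS) or a
#'   named numeric vector of RTS values for the priority genes.
#' @return data.frame with columns `cell`, `weight`, `anchor_candidate`;
#'   class `"cell_weights"`.
#' @export
assign_cell_weights <- function(expr, priority) {
  rts <- if (inherits(priority, "priority_genes")) attr(priority, "rts")
         else priority
  if (length(rts) == 0L) .stop2("empty priority gene set")
  genes <- intersect(names(rts), rownames(expr))
  if (length(genes) == 0L) .stop2("no priority gene present in expression matrix")
  sub <- expr[genes, , drop = FALSE]
  r <- rts[genes]
  pick <- function(col) {
    expressed <- which(col > 0)
    if (length(expressed) == 0L) return(NA_integer_)
    cand <- expressed[col[expressed] == max(col[expressed])]
    if (length(cand) > 1L) {
      cand <- cand[r[cand] == max(r[cand])]         # ties: higher RTS
      if (length(cand) > 1L) cand <- cand[order(genes[cand])]  # then gene id
    }
    cand[1L]
  }
  idx <- apply(sub, 2, pick)
  data.frame(cell = colnames(expr),
             weight = ifelse(is.na(idx), 0, r[idx]),
             anchor_candidate = ifelse(is.na(idx), NA_character_, genes[idx]),
             row.names = colnames(expr), stringsAsFactors = FALSE) |>
    structure(class = c("cell_weights", "data.frame"))
}

#' Superlevel-set DBSCAN decomposition of the density field
#'
#' Thresholds are `t_k = k * max(cell_density) / n_levels` for
#' `k = 0 .. n_levels - 1` (the k = 0 level keeps every cell with positive
#' density). At each threshold, DBSCAN groups the cells whose density meets
#' it into spatially separated clusters.
#'
#' @param density a `density_model` from [weighted_kde()].
#' @param embedding cells x 2 coordinate matrix.
#' @param n_levels number of contour levels (default 10).
#' @param eps DBSCAN radius; default 3x the median nearest-neighbour
#'   distance of the full embedding.
#' @param min_samples DBSCAN core-point neighbourhood size (default 5).
#' @return list with `thresholds`, `eps`, `min_samples` and `levels`: per
#'   level, `threshold`, `cells` (indices above it) and `labels` (0 =
#'   noise); class `"superlevel_clustering"`.
#' @export
superlevel_clusters <- function(density, embedding, n_levels = 10,
                                eps = NULL, min_samples = 5L) {
  if (n_levels < 2) .stop2("n_levels must be >= 2")
  if (is.null(eps)) eps <- 3 * median_nn_distance(embedding)
  dmax <- max(density$cell_density)
  thresholds <- c(0, seq_len(n_levels - 1L)) * dmax / n_levels
  levels <- vector("list", n_levels)
  for (k in seq_len(n_levels)) {
    t_k <- thresholds[k]
    cells <- if (k == 1L) which(density$cell_density > 0)
             else which(density$cell_density >= t_k)
    if (length(cells) < min_samples) {
      warning(sprintf("level %d (threshold %.4g): fewer than min_samples cells; skipped",
                      k - 1L, t_k), call. = FALSE)
      levels[[k]] <- list(threshold = t_k, cells = integer(0), labels = integer(0))
      next
    }
    labels <- dbscan_cluster(embedding[cells, , drop = FALSE], eps, min_samples)
    levels[[k]] <- list(threshold = t_k, cells = cells, labels = labels)
  }
  structure(list(thresholds = thresholds, eps = eps,
                 min_samples = as.integer(min_samples), levels = levels,
                 cell_names = rownames(embedding)),
            class = "superlevel_clustering")
}

#' Select peaks: innermost superlevel clusters
#'
#' A cluster at level k is a peak when no cluster at level k + 1 sits inside
#' it (majority containment: more than half of the higher cluster's cells
#' fall inside) and it has at least `min_cells` members - i.e. it is a local
#' density maximum with no finer structure above it. Cells belonging to
#' several selected peaks are assigned to the highest-level one; remaining
#' cells stay unassigned (deliberate data trimming).
#'
#' @param levels a `superlevel_clustering`.
#' @param min_cells minimum peak size (default 20).
#' @return data.frame of peak members with columns `cell`, `peak_id`,
#'   `level`; attribute `peaks` summarises each peak (id, level, size, mean
#'   coordinates filled by [triage_cluster()]); class `"peak_set"`.
#' @export
select_peaks <- function(levels, min_cells = 20L) {
  L <- levels$levels
  nl <- length(L)
  clusters <- list()                 # each: level k (0-based), cell indices
  for (k in seq_len(nl)) {
    lab <- L[[k]]$labels
    for (cl in setdiff(unique(lab), 0L)) {
      clusters[[length(clusters) + 1L]] <-
        list(level = k - 1L, cells = L[[k]]$cells[lab == cl])
    }
  }
  if (length(clusters) == 0L) .stop2("no peaks at current settings")
  # the size floor applies before innermost-ness: a summit shrinking below
  # min_cells does not disqualify its parent, so each density mode is
  # represented by its innermost cluster still meeting the floor
  eligible <- vapply(clusters, function(C) length(C$cells) >= min_cells, TRUE)
  is_peak <- vapply(seq_along(clusters), function(i) {
    C <- clusters[[i]]
    if (!eligible[i]) return(FALSE)
    above <- clusters[eligible & vapply(clusters, function(D)
      D$level == C$level + 1L, TRUE)]
    !any(vapply(above, function(D)
      length(intersect(D$cells, C$cells)) > length(D$cells) / 2, TRUE))
  }, TRUE)
  peaks <- clusters[is_peak]
  if (length(peaks) == 0L) .stop2("no peaks at current settings")
  ord <- order(vapply(peaks, function(p) -p$level, 0),
               vapply(peaks, function(p) min(p$cells), 0))
  peaks <- peaks[ord]
  # highest-level peak wins contested cells; order is descending level
  assigned <- integer(0)
  rows <- list()
  for (i in seq_along(peaks)) {
    mem <- setdiff(peaks[[i]]$cells, assigned)
    peaks[[i]]$cells <- mem
    assigned <- c(assigned, mem)
  }
  keep <- vapply(peaks, function(p) length(p$cells) >= min_cells, TRUE)
  peaks <- peaks[keep]
  if (length(peaks) == 0L) .stop2("no peaks at current settings")
  # stable ids: ascending level then first cell index
  ord2 <- order(vapply(peaks, function(p) p$level, 0),
                vapply(peaks, function(p) min(p$cells), 0))
  peaks <- peaks[ord2]
  ids <- sprintf("peak%02d", seq_along(peaks))
  df <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    data.frame(cell = levels$cell_names[peaks[[i]]$cells],
               peak_id = ids[i], level = peaks[[i]]$level,
               stringsAsFactors = FALSE)
  }))
  summary <- data.frame(peak_id = ids,
                        level = vapply(peaks, function(p) p$level, 0),
                        n_cells = vapply(peaks, function(p) length(p$cells), 0),
                        stringsAsFactors = FALSE)
  structure(df, peaks = summary, min_cells = as.integer(min_cells),
            class = c("peak_set", "data.frame"))
}

#' Anchor gene of a peak
#'
#' The priority gene with the highest mean expression across the peak's
#' member cells (ties resolve to the higher RTS). The anchor labels the
#' peak's identity.
#'
#' @param cells character vector of member cell ids.
#' @param expr genes x cells normalised matrix.
#' @param priority a `priority_genes` object or named RTS vector.
#' @return gene id, or `NA` with a warning when no priority gene is
#'   expressed in the peak.
#' @export
anchor_gene <- function(cells, expr, priority) {
  if (length(cells) == 0L) .stop2("empty peak")
  rts <- if (inherits(priority, "priority_genes")) attr(priority, "rts") else priority
  genes <- intersect(names(rts), rownames(expr))
  mu <- rowMeans(expr[genes, cells, drop = FALSE])
  if (all(mu <= 0)) {
    warning("no priority gene expressed in peak; anchor is NA", call. = FALSE)
    return(NA_character_)
  }
  cand <- names(mu)[mu == max(mu)]
  if (length(cand) > 1L) cand <- cand[order(-rts[cand], cand)]
  cand[1L]
}

#' Pairwise Jaccard similarity of per-peak top gene lists
#'
#' `J(p, q) = |top_p intersect top_q| / |top_p union top_q|` over the peaks'
#' top-DS gene lists.
#'
#' @param lists a `ranked_gene_lists` (from [pseudo_bulk_ds()]) or named
#'   list of character vectors.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
jaccard_similarity <- function(lists) {
  if (length(lists) < 2L) .stop2("need >= 2 peaks")
  sets <- lapply(lists, function(x) if (is.data.frame(x)) x$gene_id else as.character(x))
  if (any(lengths(sets) == 0L))
    .stop2("empty gene list for peak(s): ",
           paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  n <- length(sets)
  J <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- inter / length(union(sets[[i]], sets[[j]]))
  }
  J
}

#' Hierarchical dendrogram over peaks from Jaccard similarities
#'
#' Computes the Euclidean distance matrix between the rows of the Jaccard
#' similarity matrix and clusters it agglomeratively.
#'
#' @param similarity square symmetric similarity matrix.
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @return an `hclust` tree (leaf labels = peak ids).
#' @export
peak_dendrogram <- function(similarity, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (any(is.na(similarity))) .stop2("NaN in similarity matrix")
  if (!isTRUE(all.equal(similarity, t(similarity))))
    .stop2("similarity matrix must be symmetric")
  d <- stats::dist(similarity, method = "euclidean")
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}

#' Full TRIAGE-Cluster run
#'
#' Wires weights -> weighted KDE -> superlevel DBSCAN -> peak selection ->
#' anchors -> per-peak DS rankings -> Jaccard dendrogram.
#'
#' @param expr genes x cells normalised matrix.
#' @param embedding cells x 2 matrix (same cells).
#' @param rts_table an `rts_table`.
#' @param priority optional `priority_genes`; default computed by
#'   [select_priority_genes()] (falls back to all positive-RTS genes when
#'   the inflection method is infeasible).
#' @param bandwidth KDE bandwidth override; default [kde_bandwidth()].
#' @param n_levels,eps,min_samples,min_cells,top_n tuning knobs, see the
#'   stage functions.
#' @return list with `weights`, `density`, `levels`, `peaks` (a `peak_set`
#'   with anchor genes in its summary), `membership` (named cell -> peak
#'   vector), `rankings`, `similarity`, `dendrogram`, `params`; class
#'   `"triage_cluster_result"`.
#' @export
triage_cluster <- function(expr, embedding, rts_table, priority = NULL,
                           bandwidth = NULL, n_levels = 10, eps = NULL,
                           min_samples = 5L, min_cells = 20L, top_n = 100) {
  stopifnot(identical(sort(colnames(expr)), sort(rownames(embedding))))
  embedding <- embedding[colnames(expr), , drop = FALSE]
  if (is.null(priority)) {
    priority <- tryCatch(select_priority_genes(rts_table),
      error = function(e) {
        pos <- rts_table[rts_table$rts > 0, ]
        structure(pos$gene_id, threshold = 0, method = "fixed",
                  rts = stats::setNames(pos$rts, pos$gene_id),
                  class = "priority_genes")
      })
  }
  weights <- assign_cell_weights(expr, priority)
  density <- weighted_kde(embedding, weights$weight, h = bandwidth)
  levels <- superlevel_clusters(density, embedding, n_levels = n_levels,
                                eps = eps, min_samples = min_samples)
  peaks <- select_peaks(levels, min_cells = min_cells)
  summary <- attr(peaks, "peaks")
  summary$anchor_gene <- vapply(summary$peak_id, function(p) {
    anchor_gene(peaks$cell[peaks$peak_id == p], expr, priority)
  }, "")
  summary$x <- vapply(summary$peak_id, function(p)
    mean(embedding[peaks$cell[peaks$peak_id == p], 1]), 0)
  summary$y <- vapply(summary$peak_id, function(p)
    mean(embedding[peaks$cell[peaks$peak_id == p], 2]), 0)
  attr(peaks, "peaks") <- summary
  membership <- stats::setNames(peaks$peak_id, peaks$cell)
  rankings <- pseudo_bulk_ds(expr, membership, rts_table, top_n = top_n)
  similarity <- if (length(rankings) >= 2L) jaccard_similarity(rankings) else NULL
  dendro <- if (length(rankings) >= 3L) peak_dendrogram(similarity) else NULL
  structure(list(weights = weights, density = density, levels = levels,
                 peaks = peaks, membership = membership, rankings = rankings,
                 similarity = similarity, dendrogram = dendro,
                 params = list(bandwidth = density$h, n_levels = n_levels,
                               eps = levels$eps, min_samples = min_samples,
                               min_cells = min_cells, top_n = top_n,
                               threshold = attr(priority, "threshold"),
                               n_priority = length(priority))),
            class = "triage_cluster_result")
}

#' @export
print.triage_cluster_result <- function(x, ...) {
  s <- attr(x$peaks, "peaks")
  cat(sprintf("TRIAGE-Cluster: %d peaks over %d cells (bandwidth %.4g)\n",
              nrow(s), x$density$n, x$density$h))
  print(s, row.names = FALSE)
  invisible(x)
}
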