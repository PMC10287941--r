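## Gene-program parsing: PCA of H3K27me3 breadth (genes are observations,
## bio-samples are variables), permutation enrichment of per-gene pattern
## association, and PC selection by gene-set variance. The GMM machinery
## lives in gmm.R.

#' PCA of H3K27me3 breadth across bio-samples
#'
#' Extracts orthogonal H3K27me3 deposition patterns: genes are observations,
#' samples are variables; columns are mean-centred without variance scaling.
#'
#' @param breadth genes x samples breadth matrix.
#' @param n_pcs number of components to retain.
#' @return list with `scores` (genes x n_pcs), `loadings` (samples x n_pcs),
#'   `explained` (variance ratio per retained PC), `center`; class
#'   `"pc_model"`.
#' @export
fit_h3k27me3_pca <- function(breadth, n_pcs) {
  if (ncol(breadth) < 2L) .stop2("need >= 2 samples")
  p <- stats::prcomp(breadth, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > p$sdev[1] * 1e-12)
  if (n_pcs > rank) .stop2("n_pcs (", n_pcs, ") exceeds data rank (", rank, ")")
  structure(list(scores = p$x[, seq_len(n_pcs), drop = FALSE],
                 loadings = p$rotation[, seq_len(n_pcs), drop = FALSE],
                 explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_pcs)],
                 center = p$center, n_pcs = as.integer(n_pcs)),
            class = "pc_model")
}

#' Permutation enrichment of H3K27me3 patterns in a gene set
#'
#' Two statistics per gene and principal component. (1) A strong-association
#' flag: the gene's PC score exceeds the 95th percentile of the universe
#' (empirical right-tail p < 0.05). (2) A permutation p-value: for each of
#' `n_perm` draws of `|gene_set|` random genes from the universe outside
#' the query set, the null statistic
#' is the 95th percentile (`stat = "q95"`, default) or the maximum
#' (`stat = "max"`) of the drawn scores; `r` counts draws whose statistic
#' meets or exceeds the observed score and `p = (r + 1) / (n_perm + 1)`.
#'
#' @param pc_model a `pc_model`.
#' @param gene_set character vector of gene ids (must be in the universe).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param stat per-permutation null statistic, `"q95"` or `"max"`.
#' @param universe optional subset of genes forming the reference universe
#'   (default: all genes in the PC model).
#' @return data.frame with columns `gene_id`, `pc`, `score`, `strong`
#'   (95th-percentile flag), `r`, `p`.
#' @export
pattern_enrichment <- function(pc_model, gene_set, n_perm = 1000, seed = 0,
                               stat = c("q95", "max"), universe = NULL) {
  stat <- match.arg(stat)
  if (n_perm < 1) .stop2("n_perm must be >= 1")
  scores <- pc_model$scores
  if (!is.null(universe)) {
    missing <- setdiff(universe, rownames(scores))
    if (length(missing)) .stop2("universe gene(s) not in model: ",
                                paste(head(missing, 5), collapse = ", "))
    scores <- scores[universe, , drop = FALSE]
  }
  missing <- setdiff(gene_set, rownames(scores))
  if (length(missing))
    .stop2("gene(s) not in universe: ", paste(head(missing, 5), collapse = ", "))
  m <- ncol(scores)
  q95 <- apply(scores, 2, stats::quantile, probs = 0.95, names = FALSE)
  pool <- which(!(rownames(scores) %in% gene_set))
  if (length(pool) < length(gene_set))
    .stop2("universe outside the gene set is smaller than the gene set")
  set.seed(seed)
  draws <- replicate(n_perm, sample(pool, length(gene_set), replace = FALSE))
  stat_fun <- if (stat == "q95")
    function(v) stats::quantile(v, 0.95, names = FALSE) else max
  out <- vector("list", m)
  for (j in seq_len(m)) {
    null_stats <- apply(draws, 2, function(idx) stat_fun(scores[idx, j]))
    obs <- scores[gene_set, j]
    r <- vapply(obs, function(o) sum(null_stats >= o), 0L)
    out[[j]] <- data.frame(gene_id = gene_set, pc = colnames(scores)[j],
                           score = obs, strong = obs > q95[j],
                           r = r, p = (r + 1) / (n_perm + 1),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Rank principal components by gene-set variance and select the top m
#'
#' The PCs along which the input gene set is most spread carry the
#' H3K27me3 patterns that differentiate it; the GMM runs in their space.
#'
#' @param pc_model a `pc_model`.
#' @param gene_set character vector of >= 2 gene ids.
#' @param m number of PCs to select (default 10).
#' @return integer vector of PC indices (into the model's retained PCs),
#'   ordered by decreasing gene-set variance; attribute `variance`.
#' @export
rank_pcs_by_gene_set_variance <- function(pc_model, gene_set, m = 10) {
  if (length(gene_set) < 2L) .stop2("gene_set must have >= 2 genes")
  if (m > ncol(pc_model$scores)) .stop2("m exceeds retained PCs")
  sub <- pc_model$scores[gene_set, , drop = FALSE]
  v <- apply(sub, 2, stats::var)
  ord <- order(-v, seq_along(v))
  sel <- ord[seq_len(m)]
  structure(sel, variance = v[sel])
}

#' Full TRIAGE-ParseR run
#'
#' PCA of the breadth matrix, PC selection by gene-set variance, BIC scan
#' for the cluster number, and posterior assignment of the input genes.
#'
#' @param gene_list character vector of ranked gene ids (e.g. a peak's top
#'   100 DS genes).
#' @param breadth genes x samples breadth matrix covering the gene list.
#' @param n_pcs PCs retained from the breadth PCA.
#' @param m PCs selected by gene-set variance (features for the GMM).
#' @param theta_max,repeats,seed,tol see [scan_cluster_number()].
#' @param n_perm permutations for [pattern_enrichment()] (0 disables).
#' @return list with `pc_model`, `selected_pcs`, `scan`, `model`
#'   (a `gene_cluster_model`), `clusters` (data.frame gene/cluster/
#'   posterior), `enrichment`; class `"triage_parser_result"`.
#' @export
triage_parser <- function(gene_list, breadth, n_pcs = 10, m = 10,
                          theta_max = 10, repeats = 10, seed = 42,
                          tol = 1e-3, n_perm = 1000) {
  missing <- setdiff(gene_list, rownames(breadth))
  if (length(missing)) .stop2("gene(s) absent from breadth matrix: ",
                              paste(head(missing, 5), collapse = ", "))
  pc_model <- fit_h3k27me3_pca(breadth, n_pcs)
  sel <- rank_pcs_by_gene_set_variance(pc_model, gene_list, m = min(m, n_pcs))
  features <- pc_model$scores[gene_list, sel, drop = FALSE]
  scan <- scan_cluster_number(features, theta_max = min(theta_max, length(gene_list)),
                              repeats = repeats, seed = seed, tol = tol)
  model <- assign_gene_clusters(features, scan$theta_star, seed = seed, tol = tol)
  clusters <- data.frame(gene_id = gene_list,
                         cluster = model$assignment,
                         posterior = model$posterior[cbind(seq_along(gene_list),
                                                           model$assignment)],
                         row.names = NULL, stringsAsFactors = FALSE)
  enrichment <- if (n_perm > 0)
    pattern_enrichment(pc_model, gene_list, n_perm = n_perm, seed = seed)
    else NULL
  structure(list(pc_model = pc_model, selected_pcs = sel, scan = scan,
                 model = model, clusters = clusters, enrichment = enrichment,
                 params = list(n_pcs = n_pcs, m = m, theta_max = theta_max,
                               repeats = repeats, seed = seed, tol = tol)),
            class = "triage_parser_result")
}

#' @export
print.triage_parser_result <- function(x, ...) {
  cat(sprintf("TRIAGE-ParseR: %d genes -> %d cluster(s) (theta* by BIC over %d repeats)\n",
              nrow(x$clusters), x$scan$theta_star, x$params$repeats))
  print(table(cluster = x$clusters$cluster))
  invisible(x)
}
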