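## Benchmarking statistics: ARI, gene-removal ablation curves, Spearman
## peak-peak correlation, highly-variable-gene selection, and rank-bin
## Fisher enrichment.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model. Items are
#' matched by name when both partitions are named.
#'
#' @param a,b label vectors (named or positional) over the same item set.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0L) .stop2("partitions share no items")
    if (!setequal(names(a), names(b)))
      .stop2("partitions are over different item sets")
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) {
    .stop2("partitions are over different item sets")
  }
  mclust::adjustedRandIndex(as.character(a), as.character(b))
}

#' Priority-gene removal ablation curves
#'
#' The gold-standard partition labels each cell by its highest-expressed
#' priority gene. Genes are then removed cumulatively in steps (default 50)
#' under one of four scenarios - random draws from the priority list,
#' bottom-up by RTS rank, top-down by RTS rank, or random draws from the
#' whole gene universe - and after each step the cell labelling is
#' recomputed and compared with the gold standard by ARI. Once every
#' priority gene is gone the ARI is undefined and reported as 0 with the
#' `undefined` flag set.
#'
#' @param expr genes x cells normalised matrix.
#' @param priority a `priority_genes` object (descending RTS order).
#' @param scenario `"random_priority"`, `"bottom_up"`, `"top_down"` or
#'   `"random_genome"`.
#' @param step genes removed per step (default 50).
#' @param seed RNG seed for the random scenarios (default 0).
#' @return data.frame with columns `step`, `n_removed`, `ari`, `undefined`;
#'   attribute `scenario`.
#' @export
gene_removal_experiment <- function(expr, priority,
                                    scenario = c("random_priority", "bottom_up",
                                                 "top_down", "random_genome"),
                                    step = 50, seed = 0) {
  scenario <- match.arg(scenario)
  if (length(priority) == 0L) .stop2("empty priority gene set")
  rts <- attr(priority, "rts")
  gold <- assign_cell_weights(expr, priority)$anchor_candidate
  names(gold) <- colnames(expr)
  gold[is.na(gold)] <- ".none"
  set.seed(seed)
  removal_order <- switch(scenario,
    top_down = as.character(priority),                   # descending RTS
    bottom_up = rev(as.character(priority)),
    random_priority = sample(as.character(priority)),
    random_genome = sample(rownames(expr)))
  n_steps <- floor(length(removal_order) / step)
  out <- data.frame(step = seq_len(n_steps), n_removed = step * seq_len(n_steps),
                    ari = NA_real_, undefined = FALSE)
  for (s in seq_len(n_steps)) {
    removed <- removal_order[seq_len(step * s)]
    left <- setdiff(as.character(priority), removed)
    if (length(left) == 0L) {
      out$ari[s] <- 0; out$undefined[s] <- TRUE
      next
    }
    sub <- structure(left, rts = rts[left], class = "priority_genes")
    lab <- assign_cell_weights(expr, sub)$anchor_candidate
    names(lab) <- colnames(expr)
    lab[is.na(lab)] <- ".none"
    out$ari[s] <- adjusted_rand_index(gold, lab)
  }
  structure(out, scenario = scenario, step = step, seed = seed)
}

#' Pairwise Spearman correlation between peak profiles
#'
#' @param profiles genes x peaks matrix (e.g. average expression or DS per
#'   peak).
#' @param genes `"all"` or a character vector of gene rows (e.g. HVGs).
#' @return peaks x peaks Spearman rho matrix; constant profiles yield NA
#'   with a warning.
#' @export
spearman_peak_correlation <- function(profiles, genes = "all") {
  if (ncol(profiles) < 2L) .stop2("need >= 2 peaks")
  if (!identical(genes, "all")) profiles <- profiles[genes, , drop = FALSE]
  const <- apply(profiles, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning("constant profile(s): ", paste(colnames(profiles)[const], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  suppressWarnings(stats::cor(profiles, method = "spearman"))
}

#' Highly variable gene selection by mean-variance trend residuals
#'
#' Fits a local regression (loess) of log variance on log mean across genes
#' and ranks genes by their residual from the trend; the top `n` are the
#' highly variable set. A technical-trend approximation in the spirit of
#' the per-gene variance-modelling selectors used for scRNA-seq.
#'
#' @param expr genes x cells normalised matrix.
#' @param n number of genes to return (default 1000).
#' @return character vector of gene ids ordered by decreasing residual
#'   variance; attribute `residuals` carries all genes' residuals.
#' @export
select_hvg <- function(expr, n = 1000) {
  if (n > nrow(expr)) .stop2("n exceeds gene count")
  mu <- rowMeans(expr)
  v <- apply(expr, 1, stats::var)
  keep <- mu > 0 & v > 0
  res <- stats::setNames(rep(-Inf, nrow(expr)), rownames(expr))
  if (sum(keep) >= 10) {
    fit <- stats::loess(log(v[keep]) ~ log(mu[keep]), span = 0.75, degree = 2)
    res[keep] <- log(v[keep]) - stats::predict(fit)
  } else {
    res[keep] <- v[keep]            # too few genes for a trend: raw variance
  }
  ord <- order(-res, rownames(expr))
  structure(rownames(expr)[ord][seq_len(n)], residuals = res)
}

#' Rank-bin enrichment of a target gene set (one-tailed Fisher)
#'
#' Splits a ranked gene list into `n_bins` equal rank bins and, per bin,
#' tests over-representation of the target set against the rest of the
#' ranking with a one-tailed Fisher exact test (hypergeometric upper tail).
#'
#' @param ranking character vector of genes, best rank first (a
#'   `RankedGeneList` data.frame also works).
#' @param target_set character vector, subset of `ranking`.
#' @param n_bins number of rank bins.
#' @return data.frame with columns `bin`, `n_genes`, `n_target`,
#'   `odds_ratio`, `p` (one-tailed).
#' @export
rank_bin_enrichment <- function(ranking, target_set, n_bins = 10) {
  if (is.data.frame(ranking)) ranking <- ranking$gene_id
  if (!all(target_set %in% ranking))
    .stop2("target_set must be a subset of the ranking")
  N <- length(ranking)
  bins <- ceiling(seq_along(ranking) / (N / n_bins))
  bins <- pmin(bins, n_bins)
  if (length(unique(bins)) < n_bins) .stop2("empty bin: too many bins for list size")
  is_t <- ranking %in% target_set
  K <- sum(is_t)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    nb <- sum(bins == b)
    kb <- sum(is_t & bins == b)
    # 2x2: in-bin target / in-bin non / out-bin target / out-bin non
    or <- (kb * (N - nb - (K - kb))) / ((nb - kb) * (K - kb))
    p <- stats::phyper(kb - 1, K, N - K, nb, lower.tail = FALSE)
    data.frame(bin = b, n_genes = nb, n_target = kb,
               odds_ratio = or, p = p)
  }))
  out
}
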