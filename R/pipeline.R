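## End-to-end pipeline: RTS -> DS transform -> peak calling -> pseudo-bulk
## rankings -> gene-program parsing, with every output written as TSV /
## Newick / JSON and the fully resolved configuration recorded.

#' Run the full pipeline from files
#'
#' Stages: (1) breadth + RTS from interval files and gene models; (2)
#' normalisation and DS transform of the expression matrix; (3) peak
#' calling on the embedding; (4) per-peak pseudo-bulk DS rankings +
#' Jaccard dendrogram; (5) gene-program parsing of the largest peak's top
#' genes. Stages can be skipped; all outputs land under `out_dir` together
#' with `params.json` recording the resolved configuration so a rerun
#' reproduces deterministic outputs bit-identically.
#'
#' @param peaks_path interval input ([read_intervals()]): file, directory
#'   or manifest.
#' @param genes_path gene model file ([read_gene_models()]).
#' @param expr_path expression matrix ([read_expression()]); raw counts
#'   unless `normalise = FALSE`.
#' @param embedding_path 2D embedding file ([read_embedding()]).
#' @param out_dir output directory (created).
#' @param config named list overriding defaults: `window_halfwidth`,
#'   `breadth_mode`, `top_fraction`, `priority_method`, `fixed_threshold`,
#'   `bandwidth`, `n_levels`, `eps`, `min_samples`, `min_cells`, `top_n`,
#'   `n_pcs`, `m`, `theta_max`, `repeats`, `n_perm`, `normalise`, `seed`.
#' @param stages character subset of `c("rts","transform","cluster","parse")`.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(peaks_path, genes_path, expr_path, embedding_path,
                         out_dir, config = list(),
                         stages = c("rts", "transform", "cluster", "parse")) {
  defaults <- list(window_halfwidth = 2500, breadth_mode = "broadest",
                   top_fraction = 0.05, priority_method = "inflection",
                   fixed_threshold = NULL, bandwidth = NULL, n_levels = 10,
                   eps = NULL, min_samples = 5, min_cells = 20, top_n = 100,
                   n_pcs = 10, m = 10, theta_max = 10, repeats = 10,
                   n_perm = 1000, normalise = TRUE, seed = 42)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)

  for (p in c(peaks_path, genes_path, expr_path, embedding_path))
    if (!is.null(p) && !file.exists(p) && !dir.exists(p))
      .stop2("input not found: ", p)

  .stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      .stop2("stage '", name, "' failed: ", conditionMessage(e)))
  }

  if ("rts" %in% stages) {
    res$rts <- .stage("rts", function() {
      intervals <- read_intervals(peaks_path)
      gm <- read_gene_models(genes_path)
      breadth <- compute_gene_breadth(intervals, gm,
                                      window_halfwidth = cfg$window_halfwidth,
                                      mode = cfg$breadth_mode)
      rts <- compute_rts(breadth, top_fraction = cfg$top_fraction)
      priority <- if (cfg$priority_method == "fixed")
        select_priority_genes(rts, "fixed", cfg$fixed_threshold)
        else select_priority_genes(rts)
      write_rts(rts, file.path(out_dir, "rts.tsv"), priority)
      list(breadth = breadth, rts = rts, priority = priority)
    })
  }
  expr <- NULL
  if (any(c("transform", "cluster") %in% stages)) {
    expr <- .stage("transform", function() {
      e <- read_expression(expr_path)
      if (isTRUE(cfg$normalise)) normalize_library_size(e) else e
    })
  }
  if ("transform" %in% stages && !is.null(res$rts)) {
    res$ds <- .stage("transform", function() {
      ds <- discordance_transform(expr, res$rts$rts)
      write_expression(ds, file.path(out_dir, "ds.mtx"))
      ds
    })
  }
  if ("cluster" %in% stages) {
    res$cluster <- .stage("cluster", function() {
      emb <- read_embedding(embedding_path, cells = colnames(expr))
      cl <- triage_cluster(expr, emb, res$rts$rts, priority = res$rts$priority,
                           bandwidth = cfg$bandwidth, n_levels = cfg$n_levels,
                           eps = cfg$eps, min_samples = cfg$min_samples,
                           min_cells = cfg$min_cells, top_n = cfg$top_n)
      write_cluster_result(cl, out_dir)
      cl
    })
  }
  if ("parse" %in% stages && !is.null(res$cluster)) {
    res$parse <- .stage("parse", function() {
      summ <- attr(res$cluster$peaks, "peaks")
      top_peak <- summ$peak_id[which.max(summ$n_cells)]
      gl <- res$cluster$rankings[[top_peak]]$gene_id
      pr <- triage_parser(gl, res$rts$breadth,
                          n_pcs = min(cfg$n_pcs, ncol(res$rts$breadth) - 1),
                          m = cfg$m, theta_max = cfg$theta_max,
                          repeats = cfg$repeats, seed = cfg$seed,
                          n_perm = cfg$n_perm)
      dir.create(file.path(out_dir, "parse"), showWarnings = FALSE)
      write_tsv_meta(pr$clusters, file.path(out_dir, "parse", "clusters.tsv"),
                     list(peak = top_peak, theta_star = pr$scan$theta_star))
      write_tsv_meta(data.frame(theta = seq_len(ncol(pr$scan$bic)),
                                mean_bic = colMeans(pr$scan$bic, na.rm = TRUE)),
                     file.path(out_dir, "parse", "bic_scan.tsv"))
      if (!is.null(pr$enrichment))
        write_tsv_meta(pr$enrichment, file.path(out_dir, "parse", "enrichment.tsv"))
      pr
    })
  }
  cfg_out <- cfg
  cfg_out[vapply(cfg_out, is.null, TRUE)] <- NA
  jsonlite::write_json(cfg_out, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Write TRIAGE-Cluster outputs (peaks, density, similarity, dendrogram)
#'
#' @param cl a `triage_cluster_result`.
#' @param out_dir destination directory.
#' @export
write_cluster_result <- function(cl, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- attr(cl$peaks, "peaks")
  peaks_df <- merge(as.data.frame(cl$peaks),
                    summ[, c("peak_id", "anchor_gene")], by = "peak_id")
  peaks_df <- peaks_df[order(peaks_df$peak_id, peaks_df$cell),
                       c("cell", "peak_id", "level", "anchor_gene")]
  write_tsv_meta(peaks_df, file.path(out_dir, "peaks.tsv"),
                 cl$params[!vapply(cl$params, is.null, TRUE)])
  write_tsv_meta(data.frame(cell = names(cl$density$cell_density),
                            density = cl$density$cell_density,
                            weight = cl$weights$weight),
                 file.path(out_dir, "density.tsv"),
                 list(bandwidth = cl$density$h))
  if (!is.null(cl$similarity))
    write_tsv_meta(data.frame(peak_id = rownames(cl$similarity), cl$similarity,
                              check.names = FALSE),
                   file.path(out_dir, "similarity.tsv"))
  if (!is.null(cl$dendrogram))
    ape::write.tree(ape::as.phylo(cl$dendrogram),
                    file.path(out_dir, "dendrogram.nwk"))
  invisible(out_dir)
}
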