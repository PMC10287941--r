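## Repressive tendency score: per-gene H3K27me3 breadth across bio-samples,
## scaled breadth sum x top-5% occupancy, priority set above the knee of the
## RTS-vs-rank curve.

#' Per-gene, per-sample H3K27me3 breadth at TSS-proximal windows
#'
#' For every gene and bio-sample, measures the breadth (bp) of H3K27me3
#' intervals overlapping the window `[tss - w, tss + w]` around the gene's
#' transcription start site. With `mode = "broadest"` the broadest single
#' overlapping interval is taken (multiple peaks over a gene resolve to the
#' broadest); `mode = "total"` sums all overlapping interval lengths.
#'
#' @param intervals named list of `GRanges` per sample ([read_intervals()]).
#' @param gene_models `gene_models` data.frame ([read_gene_models()]).
#' @param window_halfwidth half-width w of the TSS window in bp (default 2500).
#' @param mode `"broadest"` (default) or `"total"`.
#' @return integer matrix genes x samples with an attribute
#'   `window_halfwidth`; class `"breadth_matrix"`.
#' @export
compute_gene_breadth <- function(intervals, gene_models,
                                 window_halfwidth = 2500,
                                 mode = c("broadest", "total")) {
  mode <- match.arg(mode)
  if (nrow(gene_models) == 0L) .stop2("empty gene set")
  w <- as.integer(window_halfwidth)
  # 0-based half-open window [tss-w, tss+w+1) -> 1-based closed coordinates
  win <- GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, gene_models$tss - w + 1L),
                              end = gene_models$tss + w + 1L))
  B <- matrix(0L, nrow = nrow(gene_models), ncol = length(intervals),
              dimnames = list(gene_models$gene_id, names(intervals)))
  any_chrom_hit <- FALSE
  for (j in seq_along(intervals)) {
    gr <- intervals[[j]]
    if (length(gr) == 0L) next
    if (any(as.character(GenomicRanges::seqnames(gr)) %in% gene_models$chrom))
      any_chrom_hit <- TRUE
    ov <- suppressWarnings(GenomicRanges::findOverlaps(win, gr))
    if (length(ov) == 0L) next
    wds <- GenomicRanges::width(gr)[S4Vectors::subjectHits(ov)]
    agg <- if (mode == "broadest") {
      tapply(wds, S4Vectors::queryHits(ov), max)
    } else {
      tapply(wds, S4Vectors::queryHits(ov), sum)
    }
    B[as.integer(names(agg)), j] <- as.integer(agg)
  }
  if (!any_chrom_hit && length(intervals) > 0L &&
      any(vapply(intervals, length, 0L) > 0L))
    warning("no chromosome shared between intervals and gene models; ",
            "breadth matrix is all zero", call. = FALSE)
  structure(B, window_halfwidth = w, mode = mode,
            class = c("breadth_matrix", class(B)))
}

#' Repressive tendency score from a breadth matrix
#'
#' Two-step score per gene: (i) sum H3K27me3 breadth over samples and scale
#' by the maximum gene (`a = breadth_sum / max(breadth_sum)`, in `[0,1]`);
#' (ii) multiply by the fraction `v` of samples in which the gene's breadth
#' is among the top 5% of broad domains in that sample. Only genes with
#' nonzero breadth compete for a sample's top tail; ties at the cut are all
#' flagged. `rts = a * v` lies in `[0,1]`.
#'
#' @param breadth genes x samples breadth matrix ([compute_gene_breadth()]).
#' @param top_fraction tail fraction defining a "broad domain" (default 0.05).
#' @return data.frame (one row per gene) with columns `gene_id`,
#'   `breadth_sum`, `a`, `v`, `rts`, sorted descending by rts (ties broken by
#'   gene_id); class `"rts_table"`.
#' @export
compute_rts <- function(breadth, top_fraction = 0.05) {
  if (ncol(breadth) < 2L) .stop2("need at least 2 samples")
  if (top_fraction <= 0 || top_fraction >= 1) .stop2("top_fraction must be in (0,1)")
  if (all(breadth == 0)) .stop2("no H3K27me3 signal: breadth matrix is all zero")
  N <- ncol(breadth)
  flags <- matrix(FALSE, nrow(breadth), N)
  for (j in seq_len(N)) {
    b <- breadth[, j]
    nz <- which(b > 0)
    if (length(nz) == 0L) next
    k <- ceiling(top_fraction * length(nz))
    cut <- sort(b[nz], decreasing = TRUE)[k]
    flags[, j] <- b >= cut & b > 0          # inclusive ties at the cut
  }
  breadth_sum <- rowSums(breadth)
  a <- breadth_sum / max(breadth_sum)
  v <- rowSums(flags) / N
  rts <- a * v
  ord <- order(-rts, rownames(breadth))
  out <- data.frame(gene_id = rownames(breadth), breadth_sum = breadth_sum,
                    a = a, v = v, rts = rts, stringsAsFactors = FALSE,
                    row.names = NULL)[ord, ]
  rownames(out) <- out$gene_id
  structure(out, top_fraction = top_fraction,
            class = c("rts_table", "data.frame"))
}

#' Look up RTS values for arbitrary genes
#'
#' Genes absent from the table get RTS 0 (unscored genes cannot rank highly
#' by discordance, by design).
#'
#' @param rts_table an `rts_table`.
#' @param genes character vector of gene ids.
#' @return named numeric vector of RTS values.
#' @export
rts_lookup <- function(rts_table, genes) {
  out <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(genes, rts_table$gene_id)
  out[hit] <- rts_table[hit, "rts"]
  out
}

#' Select the priority gene set above the RTS curve inflection point
#'
#' With `method = "inflection"`, genes are sorted by descending RTS, the
#' RTS-vs-rank curve is smoothed with a fixed-width moving average (width =
#' 1% of genes, minimum 11 ranks) and the knee is located as the point of
#' maximum perpendicular distance from the chord joining the curve's
#' endpoints. All genes ranked above the knee form the priority set; the RTS
#' at the knee is recorded as the threshold. With `method = "fixed"`, genes
#' with `rts > fixed_threshold` are returned.
#'
#' @param rts_table an `rts_table` from [compute_rts()].
#' @param method `"inflection"` (default) or `"fixed"`.
#' @param fixed_threshold RTS cutoff for `method = "fixed"`.
#' @return character vector of gene ids ordered by descending RTS, with
#'   attributes `threshold` and `method`; class `"priority_genes"`.
#' @export
select_priority_genes <- function(rts_table, method = c("inflection", "fixed"),
                                  fixed_threshold = NULL) {
  method <- match.arg(method)
  tab <- rts_table[order(-rts_table$rts, rts_table$gene_id), ]
  if (method == "fixed") {
    if (is.null(fixed_threshold)) .stop2("fixed_threshold required for method='fixed'")
    keep <- tab$rts > fixed_threshold
    if (!any(keep)) warning("no gene exceeds fixed_threshold ", fixed_threshold,
                            call. = FALSE)
    genes <- tab$gene_id[keep]
    return(structure(genes, threshold = fixed_threshold, method = "fixed",
                     rts = stats::setNames(tab$rts[keep], genes),
                     class = "priority_genes"))
  }
  pos <- tab[tab$rts > 0, ]
  if (nrow(pos) < 100L)
    .stop2("method='inflection' needs >= 100 genes with rts > 0 (have ",
           nrow(pos), "); use method='fixed'")
  y <- pos$rts
  n <- length(y)
  width <- max(11L, ceiling(0.01 * n))
  if (width %% 2 == 0) width <- width + 1L
  ys <- stats::filter(y, rep(1 / width, width), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]               # edges keep raw values
  ys <- as.numeric(ys)
  if (diff(range(ys)) < .Machine$double.eps * max(abs(ys), 1))
    .stop2("RTS curve is flat; no knee detectable - use method='fixed'")
  # max distance from the chord between (1, ys[1]) and (n, ys[n]),
  # on axes normalised to [0,1] so rank and RTS scales are comparable
  xs <- (seq_len(n) - 1) / (n - 1)
  yn <- (ys - min(ys)) / diff(range(ys))
  dx <- xs[n] - xs[1]; dy <- yn[n] - yn[1]
  d <- abs(dy * xs - dx * yn + dx * yn[1] - dy * xs[1]) / sqrt(dx^2 + dy^2)
  knee <- which.max(d)
  if (knee <= 1L || knee >= n)
    .stop2("degenerate knee at curve boundary; use method='fixed'")
  threshold <- y[knee]
  genes <- pos$gene_id[seq_len(knee - 1L)]
  genes <- genes[pos$rts[seq_len(knee - 1L)] > threshold]
  structure(genes, threshold = threshold, method = "inflection",
            knee_rank = knee,
            rts = stats::setNames(pos$rts[match(genes, pos$gene_id)], genes),
            class = "priority_genes")
}

#' @export
print.priority_genes <- function(x, ...) {
  cat(sprintf("Priority gene set: %d genes (method=%s, threshold=%.4g)\n",
              length(x), attr(x, "method"), attr(x, "threshold")))
  cat("Top genes:", paste(utils::head(unclass(x), 10), collapse = ", "), "\n")
  invisible(x)
}

#' Write an RTS table with run parameters in the preamble
#'
#' @param rts_table an `rts_table`.
#' @param priority optional `priority_genes` used to fill the `priority` column.
#' @param path destination TSV.
#' @export
write_rts <- function(rts_table, path, priority = NULL) {
  df <- as.data.frame(rts_table)
  df$priority <- if (is.null(priority)) NA else df$gene_id %in% priority
  meta <- list(top_fraction = attr(rts_table, "top_fraction"))
  if (!is.null(priority)) {
    meta$threshold <- attr(priority, "threshold")
    meta$method <- attr(priority, "method")
  }
  write_tsv_meta(df, path, meta)
}
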