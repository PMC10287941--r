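## Discordance score: log1p(normalised expression) x RTS. High DS flags
## expressed genes that are broadly repressed elsewhere - candidate identity
## regulators.

#' Library-size normalisation to the median cell total
#'
#' Scales each cell so that its total count equals the median total across
#' cells. Zero-total cells are dropped with a warning.
#'
#' @param raw_counts genes x cells non-negative matrix.
#' @return normalised matrix of the same genes; possibly fewer cells.
#' @export
normalize_library_size <- function(raw_counts) {
  if (any(raw_counts < 0)) .stop2("negative counts")
  totals <- colSums(raw_counts)
  keep <- totals > 0
  if (!any(keep)) .stop2("all cells have zero total count")
  if (any(!keep))
    warning(sum(!keep), " zero-total cell(s) dropped", call. = FALSE)
  m <- raw_counts[, keep, drop = FALSE]
  totals <- totals[keep]
  med <- stats::median(totals)
  sweep(m, 2, med / totals, `*`)
}

#' Discordance score transform
#'
#' `ds(g, c) = log(1 + expr(g, c)) * rts(g)`. Genes with zero expression or
#' zero RTS (including genes absent from the RTS table) get DS 0, so only
#' expressed, repressively tagged genes can rank highly.
#'
#' @param expr genes x cells normalised non-negative matrix.
#' @param rts an `rts_table` (or named numeric vector of RTS values).
#' @param base log base; the natural log default only rescales DS uniformly.
#' @return genes x cells DS matrix, same dimnames as `expr`.
#' @export
discordance_transform <- function(expr, rts, base = exp(1)) {
  if (any(expr < 0)) .stop2("negative expression values")
  r <- if (is.data.frame(rts)) rts_lookup(rts, rownames(expr))
       else { v <- stats::setNames(rep(0, nrow(expr)), rownames(expr))
              hit <- intersect(names(rts), rownames(expr))
              v[hit] <- rts[hit]; v }
  log1p(expr) / log(base) * r
}

#' Per-group pseudo-bulk discordance rankings
#'
#' For each peak (or any cell grouping), averages normalised expression over
#' member cells, applies the DS transform to the pseudo-bulk profile, and
#' returns the `top_n` genes ranked by descending DS (ties broken by gene
#' id).
#'
#' @param expr genes x cells normalised matrix.
#' @param membership named character/factor vector `cell -> peak id`; cells
#'   absent from it are ignored.
#' @param rts an `rts_table` or named RTS vector.
#' @param top_n list length per peak (default 100).
#' @param average `"expression"` (default: transform the mean profile) or
#'   `"ds"` (mean of per-cell DS).
#' @return named list, one data.frame (`gene_id`, `ds`) per peak, class
#'   `"ranked_gene_lists"`.
#' @export
pseudo_bulk_ds <- function(expr, membership, rts, top_n = 100,
                           average = c("expression", "ds")) {
  average <- match.arg(average)
  membership <- membership[!is.na(membership)]
  cells <- intersect(names(membership), colnames(expr))
  if (length(cells) == 0L) .stop2("no membership cell found in expression matrix")
  membership <- membership[cells]
  peaks <- sort(unique(as.character(membership)))
  out <- lapply(peaks, function(p) {
    mem <- cells[membership == p]
    if (length(mem) == 0L) .stop2("peak ", p, " has no member cells")
    prof <- if (average == "expression") {
      ds <- discordance_transform(
        matrix(rowMeans(expr[, mem, drop = FALSE]), ncol = 1,
               dimnames = list(rownames(expr), p)), rts)
      ds[, 1]
    } else {
      rowMeans(discordance_transform(expr[, mem, drop = FALSE], rts))
    }
    ord <- order(-prof, names(prof))
    head(data.frame(gene_id = names(prof)[ord], ds = prof[ord],
                    row.names = NULL, stringsAsFactors = FALSE), top_n)
  })
  names(out) <- peaks
  structure(out, top_n = top_n, class = c("ranked_gene_lists", "list"))
}
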