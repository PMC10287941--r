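## Readers and writers for the standard formats the pipeline touches.
## Internal coordinate convention: 0-based half-open throughout. GTF/GFF3
## (1-based closed) are converted on ingest; BED is native.

#' Read H3K27me3 interval files grouped by sample
#'
#' Reads one or more BED / broadPeak / bedGraph files of H3K27me3-enriched
#' intervals and returns them grouped by bio-sample. Input may be a single
#' file, a character vector of files, a directory (all files matching
#' `pattern`), or a two-column manifest TSV (`sample_id <TAB> path`).
#' Sample ids default to file stems.
#'
#' @param path file, directory, vector of files, or manifest TSV.
#' @param format one of `"BED"`, `"broadPeak"`, `"bedGraph"`.
#' @param manifest logical; force interpreting `path` as a manifest TSV.
#'   Default auto-detects: a `.tsv`/`.txt` file whose second column names
#'   existing files is treated as a manifest.
#' @param pattern glob used when `path` is a directory.
#' @return named list of [GenomicRanges::GRanges] (0-based starts stored via
#'   standard GRanges 1-based convention; use [gr_breadth()] for widths),
#'   one element per sample, class `"interval_sets"`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chrS\t100\t600\tpk1", f)
#' iv <- read_intervals(f)
#' gr_breadth(iv[[1]]) # 500
#' @export
read_intervals <- function(path, format = c("BED", "broadPeak", "bedGraph"),
                           manifest = NA, pattern = "\\.(bed|broadPeak|bedgraph|bdg)$") {
  format <- match.arg(format)
  files <- .resolve_sample_files(path, manifest, pattern)
  out <- lapply(names(files), function(sid) .read_interval_file(files[[sid]], format))
  names(out) <- names(files)
  structure(out, class = c("interval_sets", "list"))
}

.resolve_sample_files <- function(path, manifest, pattern) {
  if (length(path) > 1L) {
    files <- as.list(path)
    names(files) <- .file_stem(path)
    return(files)
  }
  if (dir.exists(path)) {
    fs <- sort(list.files(path, pattern = pattern, full.names = TRUE, ignore.case = TRUE))
    if (length(fs) == 0L) .stop2("no interval files found under directory: ", path)
    files <- as.list(fs)
    names(files) <- .file_stem(fs)
    return(files)
  }
  if (!file.exists(path)) .stop2("no such file: ", path)
  is_manifest <- isTRUE(manifest)
  if (is.na(manifest) && grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    probe <- tryCatch(read.table(path, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE, nrows = 5, comment.char = "#"),
                      error = function(e) NULL)
    if (!is.null(probe) && ncol(probe) >= 2 && all(file.exists(
          ifelse(file.exists(probe[[2]]), probe[[2]],
                 file.path(dirname(path), probe[[2]])))))
      is_manifest <- TRUE
  }
  if (is_manifest) {
    man <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(man) < 2) .stop2("manifest must have columns sample_id<TAB>path: ", path)
    paths <- ifelse(file.exists(man[[2]]), man[[2]], file.path(dirname(path), man[[2]]))
    missing <- !file.exists(paths)
    if (any(missing)) .stop2("manifest references missing files: ",
                             paste(man[[2]][missing], collapse = ", "))
    files <- as.list(paths)
    names(files) <- as.character(man[[1]])
    return(files)
  }
  stats::setNames(list(path), .file_stem(path))
}

.file_stem <- function(p) sub("\\.[^.]*$", "", basename(p))

.read_interval_file <- function(file, format) {
  n_lines <- length(readLines(file, warn = FALSE))
  if (n_lines == 0L) {
    warning("empty interval file: ", file, call. = FALSE)
    return(GenomicRanges::GRanges())
  }
  gr <- tryCatch({
    switch(format,
      BED       = rtracklayer::import(file, format = "BED"),
      bedGraph  = rtracklayer::import(file, format = "bedGraph"),
      broadPeak = rtracklayer::import(file, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric")))
  }, error = function(e) {
    .stop2("failed to parse ", file, " as ", format, ": ", conditionMessage(e))
  })
  if (length(gr) && any(GenomicRanges::width(gr) < 1))
    .stop2("interval with end <= start in ", file)
  gr
}

#' Breadth (bp) of intervals under the half-open convention
#'
#' @param gr a `GRanges`.
#' @return integer vector of interval lengths in bp.
#' @export
gr_breadth <- function(gr) GenomicRanges::width(gr)

#' Read gene models (TSS and strand)
#'
#' Parses GTF/GFF3 (via rtracklayer, converting to 0-based) or a 4-column TSV
#' (`gene_id chrom strand tss`, TSS already 0-based) into one record per
#' gene. For stranded annotation spans, the TSS is the leftmost coordinate on
#' `+` and the rightmost-minus-one on `-`. Duplicate gene ids keep the first
#' record; the number of collisions is reported.
#'
#' @param path annotation file.
#' @param format `"GTF"`, `"GFF3"` or `"TSV"` (default guessed from extension).
#' @param feature for GTF/GFF3, the feature type used (`"gene"` falling back
#'   to `"transcript"` then any).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based), class `"gene_models"`.
#' @export
read_gene_models <- function(path, format = NULL, feature = "gene") {
  if (is.null(format)) {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "GTF"
      else if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "GFF3"
      else "TSV"
  }
  format <- match.arg(format, c("GTF", "GFF3", "TSV"))
  if (format == "TSV") {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                     comment.char = "#")
    need <- c("gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(df)))
      .stop2("gene model TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
  } else {
    gr <- rtracklayer::import(path, format = tolower(format))
    keep <- as.character(gr$type) == feature
    if (!any(keep)) keep <- as.character(gr$type) == "transcript"
    if (!any(keep)) keep <- rep(TRUE, length(gr))
    gr <- gr[keep]
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*"))
      .stop2("gene model records without strand in ", path)
    ids <- gr$gene_id
    if (is.null(ids)) ids <- gr$ID
    if (is.null(ids)) .stop2("no gene_id attribute in ", path)
    # GRanges is 1-based closed; 0-based TSS is start-1 (+) or end-1 (-)
    tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                  GenomicRanges::end(gr) - 1L)
    df <- data.frame(gene_id = as.character(ids),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = strand, tss = as.integer(tss),
                     stringsAsFactors = FALSE)
  }
  if (!all(df$strand %in% c("+", "-")))
    .stop2("invalid strand values in ", path)
  if (any(df$tss < 0)) .stop2("negative TSS in ", path)
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    .log_msg(sum(dup), " duplicate gene_id record(s) dropped (first kept)")
    df <- df[!dup, ]
  }
  rownames(df) <- df$gene_id
  structure(df, class = c("gene_models", "data.frame"))
}

#' Read a normalised gene x cell expression matrix
#'
#' Supports MatrixMarket triplets with `genes.tsv`/`barcodes.tsv` sidecars
#' (give the `.mtx` path; sidecars are looked up next to it, or supply
#' `genes`/`cells` paths) and dense TSV with gene ids in the first column and
#' cell ids in the header.
#'
#' @param path `.mtx` or dense `.tsv` file.
#' @param genes,cells optional sidecar paths for MTX input.
#' @return numeric matrix (genes x cells, dimnames set). Zero rows retained.
#' @export
read_expression <- function(path, genes = NULL, cells = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(genes)) genes <- file.path(dirname(path), "genes.tsv")
    if (is.null(cells)) cells <- file.path(dirname(path), "barcodes.tsv")
    g <- readLines(genes); g <- g[nzchar(g)]
    b <- readLines(cells); b <- b[nzchar(b)]
    g <- vapply(strsplit(g, "\t"), `[[`, "", 1L)
    b <- vapply(strsplit(b, "\t"), `[[`, "", 1L)
    if (length(g) != nrow(m))
      .stop2("gene sidecar has ", length(g), " ids but matrix has ", nrow(m), " rows")
    if (length(b) != ncol(m))
      .stop2("cell sidecar has ", length(b), " ids but matrix has ", ncol(m), " columns")
    dimnames(m) <- list(g, b)
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                     check.names = FALSE, comment.char = "#")
    m <- as.matrix(df)
  }
  .validate_expression(m)
  m
}

.validate_expression <- function(m) {
  if (anyDuplicated(rownames(m))) .stop2("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) .stop2("duplicate cell identifiers")
  if (any(m < 0)) .stop2("negative expression values")
  invisible(m)
}

#' Write an expression matrix as MTX + sidecars or dense TSV
#'
#' @param m genes x cells matrix with dimnames.
#' @param path `.mtx` or `.tsv` destination.
#' @export
write_expression <- function(m, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                            "CsparseMatrix"), "generalMatrix"), path)
    writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  } else {
    .write_tsv(data.frame(gene = rownames(m), m, check.names = FALSE), path)
  }
  invisible(path)
}

#' Read a precomputed 2D embedding
#'
#' CSV or TSV with cell ids in the first column and two coordinate columns.
#'
#' @param path embedding file.
#' @param cells optional character vector the embedding's cell set must equal.
#' @return numeric matrix (cells x 2) with rownames = cell ids.
#' @export
read_embedding <- function(path, cells = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 3) .stop2("embedding needs id + 2 coordinate columns")
  emb <- as.matrix(df[, 2:3])
  rownames(emb) <- as.character(df[[1]])
  if (ncol(emb) != 2) .stop2("embedding must be exactly 2-dimensional")
  if (!is.null(cells)) {
    if (!setequal(rownames(emb), cells))
      .stop2("embedding cell set differs from expression matrix cell set")
    emb <- emb[cells, , drop = FALSE]
  }
  emb
}

#' Write a TSV with a `#` metadata preamble
#'
#' All tabular outputs of the pipeline use this format: `# key=value`
#' preamble lines followed by a header line and tab-separated rows.
#'
#' @param df data.frame to write.
#' @param path destination.
#' @param meta named list serialised into the preamble.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, paste(format(meta[[k]]), collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_tsv <- function(df, path) write_tsv_meta(df, path, list())

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path file to read.
#' @return data.frame; preamble returned in attribute `"meta"`.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  pre <- grep("^#", lines)
  meta <- list()
  if (length(pre)) {
    kv <- sub("^#\\s*", "", lines[pre])
    kv <- strsplit(kv, "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                            vapply(kv, `[[`, "", 1L))
  }
  df <- read.table(text = lines[setdiff(seq_along(lines), pre)], sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write interval sets as per-sample BED files
#'
#' @param intervals named list of `GRanges` as from [read_intervals()].
#' @param dir output directory (created).
#' @return invisible vector of written paths.
#' @export
write_intervals <- function(intervals, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(intervals), function(sid) {
    p <- file.path(dir, paste0(sid, ".bed"))
    rtracklayer::export(intervals[[sid]], p, format = "BED")
    p
  }, "")
  invisible(paths)
}
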