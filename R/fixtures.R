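## Seed-deterministic synthetic data generators: a pseudo-epigenome with
## planted broad-domain regulatory genes, a toy single-cell atlas with known
## cell types, and spherical Gaussian clusters in PC space. Every generator
## returns its ground truth alongside the data and can serialise both.

#' Simulate an H3K27me3 pseudo-epigenome with planted regulatory genes
#'
#' Genes sit on one synthetic chromosome `chrS`, spaced so TSS windows
#' cannot overlap. `n_regulatory` planted genes receive a broad H3K27me3
#' domain spanning their TSS in at least `regulatory_sample_fraction` of
#' pseudo-samples; remaining genes receive narrow domains in a minority of
#' samples (or none), so the planted genes are the only consistently broad
#' loci. Among the planted genes, domain breadth declines with gene index
#' (`regG0001` broadest), emulating the observed coupling between breadth
#' rank and cell-type specificity: the paired atlas generator's marker
#' genes are the lowest-index (hence highest-RTS) planted genes.
#'
#' @param n_genes total genes.
#' @param n_samples pseudo-samples (bio-samples).
#' @param n_regulatory planted regulatory genes (the first
#'   `n_regulatory` gene ids, `regG0001...`).
#' @param broad_breadth_range bp range for broad domains (default
#'   10000-30000).
#' @param narrow_breadth_range bp range for narrow domains (default
#'   200-2000); must lie strictly below the broad range.
#' @param regulatory_sample_fraction fraction of samples in which a planted
#'   gene carries a broad domain (default 0.9).
#' @param background_sample_fraction fraction of samples in which a
#'   background gene carries a narrow domain (default 0.9; a large nonzero
#'   universe keeps the per-sample top-5% tail wider than the planted set).
#' @param window_halfwidth TSS window half-width used to set gene spacing.
#' @param seed RNG seed.
#' @param dir optional directory: BED files per sample plus `truth.json`
#'   are written there.
#' @return list with `intervals` (named list of `GRanges`), `gene_models`,
#'   `truth` (planted genes, parameters, seed).
#' @export
simulate_epigenome <- function(n_genes = 1500, n_samples = 16, n_regulatory = 50,
                               broad_breadth_range = c(10000, 30000),
                               narrow_breadth_range = c(200, 2000),
                               regulatory_sample_fraction = 0.9,
                               background_sample_fraction = 0.9,
                               window_halfwidth = 2500, seed = 0, dir = NULL) {
  if (n_regulatory >= n_genes) .stop2("n_regulatory must be < n_genes")
  if (max(narrow_breadth_range) >= min(broad_breadth_range))
    .stop2("broad breadth range must lie strictly above the narrow range")
  set.seed(seed)
  spacing <- 2L * window_halfwidth + max(broad_breadth_range) + 1000L
  ids <- c(sprintf("regG%04d", seq_len(n_regulatory)),
           sprintf("bgG%04d", seq_len(n_genes - n_regulatory)))
  tss <- as.integer(seq_len(n_genes)) * spacing
  gene_models <- structure(
    data.frame(gene_id = ids, chrom = "chrS",
               strand = rep(c("+", "-"), length.out = n_genes), tss = tss,
               stringsAsFactors = FALSE, row.names = ids),
    class = c("gene_models", "data.frame"))
  samples <- sprintf("sample%02d", seq_len(n_samples))
  intervals <- lapply(samples, function(s) {
    starts <- ends <- integer(0)
    for (g in seq_len(n_genes)) {
      reg <- g <= n_regulatory
      hit <- stats::runif(1) < if (reg) regulatory_sample_fraction
                               else background_sample_fraction
      if (!hit) next
      breadth <- if (reg) {
        # breadth declines with planted-gene index, jittered within a
        # sliding 1/n_regulatory-wide slice of the broad range
        span <- diff(broad_breadth_range)
        round(broad_breadth_range[1] +
                span * (n_regulatory - g + stats::runif(1)) / n_regulatory)
      } else {
        round(stats::runif(1, narrow_breadth_range[1], narrow_breadth_range[2]))
      }
      # centre the domain on the TSS (0-based half-open)
      s0 <- max(0L, tss[g] - as.integer(breadth %/% 2))
      starts <- c(starts, s0); ends <- c(ends, s0 + as.integer(breadth))
    }
    if (length(starts) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("chrS", IRanges::IRanges(start = starts + 1L, end = ends))
  })
  names(intervals) <- samples
  intervals <- structure(intervals, class = c("interval_sets", "list"))
  truth <- list(regulatory_genes = ids[seq_len(n_regulatory)],
                params = list(n_genes = n_genes, n_samples = n_samples,
                              n_regulatory = n_regulatory,
                              broad_breadth_range = broad_breadth_range,
                              narrow_breadth_range = narrow_breadth_range,
                              regulatory_sample_fraction = regulatory_sample_fraction,
                              background_sample_fraction = background_sample_fraction,
                              window_halfwidth = window_halfwidth),
                seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_intervals(intervals, dir)
    write_tsv_meta(as.data.frame(gene_models), file.path(dir, "genes.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  list(intervals = intervals, gene_models = gene_models, truth = truth)
}

#' Simulate a toy single-cell atlas with known cell types
#'
#' Counts are negative binomial with per-type mean shifts on marker genes;
#' the 2D embedding places each type's cells in a Gaussian blob with centre
#' separation `embedding_separation` and spread `noise_sd`. Library sizes
#' vary log-normally so the normaliser is exercised.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells per type.
#' @param n_genes total genes (ids must cover `marker_map` genes).
#' @param marker_map named list: cell type -> character vector of marker
#'   (planted regulatory) gene ids. Default: type `i` gets markers
#'   `regG[(i-1)*5 + 1 .. i*5]`.
#' @param gene_ids optional gene id vector (default `regG...`/`bgG...`
#'   matching [simulate_epigenome()]).
#' @param embedding_separation distance between adjacent blob centres.
#' @param noise_sd blob spread (default 1).
#' @param marker_fold expression fold-up of a type's markers (default 20).
#' @param base_mean baseline NB mean (default 2).
#' @param dispersion NB size parameter (default 0.5).
#' @param libsize_sd log-normal sd of library-size factors (default 0.3).
#' @param seed RNG seed.
#' @return list with `counts` (genes x cells), `embedding` (cells x 2),
#'   `labels` (named true types), `marker_map`, `truth`.
#' @export
simulate_atlas <- function(n_cell_types = 3, cells_per_type = 150,
                           n_genes = 600, marker_map = NULL, gene_ids = NULL,
                           embedding_separation = 10, noise_sd = 1,
                           marker_fold = 20, base_mean = 2, dispersion = 0.5,
                           libsize_sd = 0.3, seed = 0) {
  if (embedding_separation <= 0) .stop2("embedding_separation must be positive")
  set.seed(seed)
  if (is.null(gene_ids))
    gene_ids <- c(sprintf("regG%04d", seq_len(min(50, n_genes %/% 2))),
                  sprintf("bgG%04d", seq_len(n_genes - min(50, n_genes %/% 2))))
  if (is.null(marker_map)) {
    marker_map <- lapply(seq_len(n_cell_types), function(i)
      sprintf("regG%04d", ((i - 1) * 5 + 1):(i * 5)))
    names(marker_map) <- sprintf("type%d", seq_len(n_cell_types))
  }
  if (!all(unlist(marker_map) %in% gene_ids))
    .stop2("marker_map genes must be in gene_ids")
  types <- names(marker_map)
  n_cells <- n_cell_types * cells_per_type
  cells <- sprintf("cell%04d", seq_len(n_cells))
  labels <- stats::setNames(rep(types, each = cells_per_type), cells)
  counts <- matrix(0, n_genes, n_cells, dimnames = list(gene_ids, cells))
  lib <- exp(stats::rnorm(n_cells, 0, libsize_sd))
  for (ci in seq_len(n_cells)) {
    mu <- rep(base_mean, n_genes)
    names(mu) <- gene_ids
    mu[marker_map[[labels[ci]]]] <- base_mean * marker_fold
    counts[, ci] <- stats::rnbinom(n_genes, size = dispersion,
                                   mu = mu * lib[ci])
  }
  # blob centres on a circle of radius r giving adjacent separation ~ sep
  if (n_cell_types == 1L) {
    centres <- matrix(0, 1, 2)
  } else {
    angle <- 2 * pi * (seq_len(n_cell_types) - 1) / n_cell_types
    r <- embedding_separation / (2 * sin(pi / n_cell_types))
    centres <- cbind(r * cos(angle), r * sin(angle))
  }
  embedding <- centres[rep(seq_len(n_cell_types), each = cells_per_type), ] +
    matrix(stats::rnorm(2 * n_cells, 0, noise_sd), n_cells, 2)
  rownames(embedding) <- cells
  colnames(embedding) <- c("dim1", "dim2")
  truth <- list(labels = labels, marker_map = marker_map,
                params = list(n_cell_types = n_cell_types,
                              cells_per_type = cells_per_type,
                              n_genes = n_genes,
                              embedding_separation = embedding_separation,
                              noise_sd = noise_sd, marker_fold = marker_fold,
                              base_mean = base_mean, dispersion = dispersion,
                              libsize_sd = libsize_sd),
                seed = seed)
  list(counts = counts, embedding = embedding, labels = labels,
       marker_map = marker_map, truth = truth)
}

#' Simulate spherical Gaussian gene clusters in PC space
#'
#' @param n_genes observations (default 100).
#' @param n_clusters planted clusters.
#' @param dim feature dimensionality (default 10).
#' @param separation centre separation in sd units (cluster sd = 1).
#' @param seed RNG seed.
#' @return list with `features` (genes x dim), `labels` (true cluster per
#'   gene), `truth`.
#' @export
simulate_pc_clusters <- function(n_genes = 100, n_clusters = 3, dim = 10,
                                 separation = 8, seed = 0) {
  if (dim < 1) .stop2("dim must be >= 1")
  if (n_clusters > n_genes) .stop2("n_clusters must be <= n_genes")
  set.seed(seed)
  # orthogonal-ish centres: cluster j offset along axis (j mod dim)
  centres <- matrix(0, n_clusters, dim)
  for (j in seq_len(n_clusters))
    centres[j, ((j - 1) %% dim) + 1] <- (j - 1) * separation
  sizes <- rep(n_genes %/% n_clusters, n_clusters)
  sizes[seq_len(n_genes %% n_clusters)] <- sizes[seq_len(n_genes %% n_clusters)] + 1L
  labels <- rep(seq_len(n_clusters), times = sizes)
  features <- centres[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_genes * dim), n_genes, dim)
  rownames(features) <- sprintf("gene%04d", seq_len(n_genes))
  list(features = features,
       labels = stats::setNames(labels, rownames(features)),
       truth = list(params = list(n_genes = n_genes, n_clusters = n_clusters,
                                  dim = dim, separation = separation),
                    seed = seed))
}

#' Synthetic breadth matrix with planted deposition programs
#'
#' Builds a genes x samples H3K27me3 breadth matrix in which disjoint gene
#' blocks follow distinct sample-profile "programs" (plus background
#' noise), for end-to-end testing of the gene-program parser.
#'
#' @param n_genes total genes; `n_program_genes` per program are planted.
#' @param n_samples bio-samples.
#' @param n_programs planted deposition programs.
#' @param n_program_genes genes per program.
#' @param amplitude breadth amplitude of a program over its samples (bp).
#' @param noise_sd additive noise sd (bp).
#' @param seed RNG seed.
#' @return list with `breadth` (genes x samples, non-negative),
#'   `program` (named gene -> program id, 0 = background), `truth`.
#' @export
simulate_breadth_programs <- function(n_genes = 500, n_samples = 40,
                                      n_programs = 3, n_program_genes = 34,
                                      amplitude = 20000, noise_sd = 500,
                                      seed = 0) {
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  program <- stats::setNames(rep(0L, n_genes), genes)
  # each program occupies a disjoint third of the samples
  blocks <- split(seq_len(n_samples),
                  rep(seq_len(n_programs), length.out = n_samples))
  B <- matrix(pmax(0, stats::rnorm(n_genes * n_samples, 1000, noise_sd)),
              n_genes, n_samples,
              dimnames = list(genes, sprintf("sample%02d", seq_len(n_samples))))
  for (p in seq_len(n_programs)) {
    idx <- ((p - 1) * n_program_genes + 1):(p * n_program_genes)
    program[idx] <- p
    B[idx, blocks[[p]]] <- B[idx, blocks[[p]]] + amplitude
  }
  list(breadth = round(B), program = program,
       truth = list(params = list(n_genes = n_genes, n_samples = n_samples,
                                  n_programs = n_programs,
                                  n_program_genes = n_program_genes,
                                  amplitude = amplitude, noise_sd = noise_sd),
                    seed = seed))
}
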