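# triager

Cell populations in single-cell RNA-seq data are usually called by
expression similarity alone, treating every cell and every gene as equally
informative. `triager` takes a different anchor: genes that control cell
identity are *broadly repressed* elsewhere, and that repression is visible
as broad H3K27me3 domains across consortium-scale epigenomic data. The
package quantifies this per gene, weights cells by it, and uses the
weighted density over a 2D embedding to call cell-population peaks — then
decomposes each peak's top genes into epigenetically coherent programs.

It is aimed at computational biologists analysing scRNA-seq with access to
H3K27me3 peak calls (e.g. consortium BED files), and at method developers
who want a reproducible, fixture-tested implementation of the underlying
statistics.

## The scores and the pipeline

**RTS** (repressive tendency score), per gene over `N` bio-samples, from
H3K27me3 breadth `b_gs` at the TSS ± 2.5 kb:

    RTS_g = a_g * v_g
    a_g   = sum_s b_gs / max_g' sum_s b_g's          (scaled breadth sum)
    v_g   = #{s : b_gs in sample s's top 5%} / N     (broad-domain occupancy)

Genes above the knee of the RTS-vs-rank curve form the **priority set**.

**DS** (discordance score), per gene and cell of a normalised expression
matrix `x`: `DS_gc = ln(1 + x_gc) * RTS_g` — high DS flags expressed genes
that are usually repressed, i.e. candidate identity regulators.

**TRIAGE-Cluster**: each cell is weighted by the RTS of its
highest-expressed priority gene; a weighted Gaussian KDE
(`h = 0.3 * n^(-1/6)` by default) over the embedding is cut at 10 density
levels; DBSCAN clusters each superlevel set; innermost clusters of at
least 20 cells are **peaks**, each labelled by its **anchor gene** and
compared to other peaks via Jaccard similarity of top-100 DS genes.

**TRIAGE-ParseR**: genes x samples breadth PCA → the 10 PCs most variable
within the input gene list → diagonal-covariance Gaussian mixture, cluster
number chosen by BIC over repeated EM runs → posterior gene assignments,
plus permutation enrichment of each gene's H3K27me3 patterns.

## Worked example

Everything below runs on the package's own synthetic generators, so it is
fully reproducible without downloads:

```r
library(triager)

## RTS from a simulated epigenome with 50 planted broad-domain genes
epi <- simulate_epigenome(seed = 0)
b   <- compute_gene_breadth(epi$intervals, epi$gene_models)   # genes x samples, bp
rts <- compute_rts(b)
head(as.data.frame(rts), 5)
#>           gene_id breadth_sum     a     v   rts
#> regG0002 regG0002      440983 1.000 0.938 0.938
#> regG0012 regG0012      406767 0.922 1.000 0.922
#> regG0004 regG0004      429068 0.973 0.938 0.912
#> regG0005 regG0005      423240 0.960 0.938 0.900
#> regG0007 regG0007      411124 0.932 0.938 0.874

select_priority_genes(rts)
#> Priority gene set: 55 genes (method=inflection, threshold=0.005585)
#> Top genes: regG0002, regG0012, regG0004, regG0005, regG0007, ...

## Peak calling on a 3-type synthetic atlas
a  <- simulate_atlas(seed = 0)
cl <- triage_cluster(normalize_library_size(a$counts), a$embedding, rts,
                     bandwidth = 0.3)
cl
#> TRIAGE-Cluster: 3 peaks over 450 cells (bandwidth 0.3)
#>  peak_id level n_cells anchor_gene         x          y
#>   peak01     6      42    regG0005  5.591476 -0.2386177
#>   peak02     8      20    regG0008 -3.220162  4.9287092
#>   peak03     8      23    regG0014 -2.700093 -4.7554594
adjusted_rand_index(a$labels[names(cl$membership)], cl$membership)
#> [1] 1

## Gene-program parsing of a 102-gene list over planted deposition programs
bp <- simulate_breadth_programs(seed = 0)
gl <- names(bp$program)[bp$program > 0]
triage_parser(gl, bp$breadth, theta_max = 8)
#> TRIAGE-ParseR: 102 genes -> 3 cluster(s) (theta* by BIC over 10 repeats)
#> cluster
#>  1  2  3
#> 34 34 34
```

Each peak's `anchor_gene` is one of the planted markers of the cell type
it recovered; the ARI of 1 means peak membership matches the planted cell
types exactly on every assigned cell; the parser's three 34-gene clusters
are the three planted deposition programs.

The methods vignette (`vignettes/triager-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, what the
generators do and do not emulate, and the numerical edge-case policies.
A thin command-line wrapper over the same functions lives at
`inst/cli/triage.R` (subcommands `rts`, `transform`, `pseudobulk`,
`cluster`, `parse`, `simulate`, `pipeline`).

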