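# dotscape

Multi-channel dot plots for multifaceted omics data.

## The problem

Dot plots are the workhorse for per-cluster marker summaries in single-cell
RNA-seq: a grid of genes × cell clusters where dot size shows the
percentage of expressing cells and dot color the average scaled expression.
Most implementations stop there — two quantitative channels, tied to one
pipeline's output format. Real analyses routinely need to overlay more:
which genes are canonical markers, a gene's CNV status per patient, a
second modality's (ADT) percentages, or per-partner expression in
cell–cell-interaction plots.

`dotscape` is a universal dot-plot engine for anyone with a long-format
table. Each row is an (x level, y level) pair plus 1–4 display factors,
quantitative or qualitative; the engine maps them onto four glyph channels:

| channel | quantitative factor | qualitative factor |
|---------|--------------------|--------------------|
| size    | area ∝ value (linear in area, clamped) | *rejected* — area is ordered |
| color   | linear RGB gradient (symmetric around 0 for z-scores) | discrete palette by level |
| text    | rounded label in the dot | verbatim label |
| shape   | filled circular sector, angle = 2π·fraction | one symbol per level |

The quantitative *shape* channel — a disc filled in proportion to the value
— is the distinctive glyph: it reads directly as a percentage, freeing size
and color for other quantities.

Axis levels can be reordered by hierarchical clustering (Ward, complete,
average or single linkage) of their factor profiles, embedded first by the
type-appropriate factor analysis: **PCA** for quantitative profiles,
**MCA** (correspondence analysis of the indicator matrix) for qualitative
ones, and **FAMD** for a mix. Dendrograms are drawn alongside the grid and
exportable as Newick.

A summarization adaptor turns a genes × cells expression matrix plus
cluster labels into the canonical table: `Pct.exp` (percent of cells in the
cluster with expression above a threshold) and `Avg.scaled.exp` (per-gene
z-score across all cells, averaged within the cluster).

Output is a byte-deterministic SVG (identical input ⇒ identical bytes) or a
ggplot2 object you can extend with further layers, plus PNG rasterization.

## Worked example

```r
library(dotscape)

# simulate a clustered expression matrix with cluster-specific markers
fx <- synthetic_expression(n_genes = 20, n_cells = 300, n_clusters = 3, seed = 1)
flag <- setNames(rep("other", 20), rownames(fx$matrix))
flag[fx$markers$gene] <- "marker"

# summarize per (gene, cluster) and attach the marker flag
tab <- build_dot_table(fx$matrix, fx$clusters, extra = list(marker = flag))
tab
#> <dot_table> 60 rows; 3 x-levels x 20 y-levels; 3 display factor(s)
#>   Pct.exp [quantitative]
#>   Avg.scaled.exp [quantitative]
#>   marker [qualitative]
#>   Cluster   Gene Pct.exp Avg.scaled.exp marker
#> 1      c1 gene01      61    -0.41589873 marker
#> 2      c1 gene02      58    -0.46596531 marker
#> 3      c1 gene03      55     0.12417270  other
#> 4      c1 gene04      50    -0.48768254 marker
#> 5      c1 gene05      55    -0.02988428  other
#> 6      c1 gene06      56     0.14936133  other

# bind all four channels and cluster both axes
spec <- channel_spec(size = "Pct.exp", color = "Avg.scaled.exp",
                     text = "Pct.exp", shape = "marker")
scene <- compose(tab, spec,
                 row_dend = order_axis(tab, "y"),
                 col_dend = order_axis(tab, "x"))
scene
#> <dot_scene> 325 x 870 pt; 60 glyphs (3 x-levels x 20 y-levels)

render(scene, "markers.svg")      # deterministic SVG
gg <- as_ggplot(scene)            # extensible ggplot2 handle
```

Each of the 60 dots is one (cluster, gene) pair: its area and text show the
percent of cells expressing the gene in that cluster (e.g. `61` = 61% of
cluster c1 expresses gene01), its color the cluster's mean z-scored
expression (blue below the gene's overall mean, red above, white at 0), and
its outline whether the gene is a simulated marker (circle) or not
(square). Rows and columns are ordered by Ward clustering on PCA
coordinates of the quantitative profiles.

The same flow from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dotscape.R", package = "dotscape"))')
Rscript "$CLI" fixtures  --out-dir fx --n-genes 20 --n-cells 300 --n-clusters 3 --seed 1
Rscript "$CLI" summarize --matrix fx/matrix.mtx --genes fx/genes.txt \
    --cells fx/cells.txt --clusters fx/clusters.csv --markers fx/markers.csv \
    --out fx/summary.csv
Rscript "$CLI" plot --input fx/summary.csv --size-col Pct.exp \
    --color-col Avg.scaled.exp --text-col Pct.exp --shape-col marker \
    --row-dend --col-dend --out markers.svg
```

For cell-communication tables, `split_columns()` divides each interaction
column (e.g. `TAM|TP1`) into two adjacent sub-columns carrying each
partner's own expression.

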