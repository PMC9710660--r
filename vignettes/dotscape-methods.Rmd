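---
title: "Multi-channel dot plots: models, encodings and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel dot plots: models, encodings and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotscape)
```

## The visualization model

A dot plot is a heatmap variant in which each cell of an (x, y) category
grid is a glyph rather than a colored box. Where a heatmap communicates a
single quantity per cell, a dot glyph has four independent channels:

* **size** — the glyph's area;
* **color** — its fill;
* **text** — a short label drawn inside it;
* **shape** — its outline, or, for quantitative factors, how much of a disc
  is filled.

`dotscape` maps up to four *display factors* of a long-format table onto
these channels. The input contract is deliberately minimal: column 1 holds
the x-axis levels, column 2 the y-axis levels, and columns 3 onward the
display factors, each either quantitative (parses as a finite real) or
qualitative (an unordered label). This is the format every downstream
pipeline can emit — per-cluster gene summaries from scRNA-seq, CNV calls,
cell–cell interaction scores — without adapters specific to any upstream
tool.

One compatibility rule is enforced: **size accepts only quantitative
factors**. Area is an inherently ordered visual variable; binding unordered
labels to it would invite false readings. Color, text and shape accept
either kind with an adapted rendering.

A factor may drive several channels at once (a percentage shown as both
area and text is the canonical scRNA-seq usage); each channel takes at most
one factor.

## Channel encodings

**Size.** Values map *linearly to area*, not radius:
`area = min_area + (v − lo)/(hi − lo) · (max_area − min_area)`, clamped to
`[min_area, max_area]` (defaults 4–420 pt²). Human area perception is what
makes a "percent of cells" dot readable; a radius-linear map would inflate
differences quadratically. Values outside the domain are clamped; a missing
value omits the glyph entirely when size is bound, which visually separates
"absent" from "zero".

**Color.** Quantitative factors interpolate piecewise-linearly in RGB
between anchor colors. The default palette is blue–white–red, symmetric
around 0 whenever negatives are present — the natural choice for z-scored
expression, where 0 must land exactly on the middle anchor — and
white→blue otherwise. Qualitative factors cycle a colorblind-safe discrete
palette in level order (recycling warns). Missing values render neutral
grey.

**Text.** Quantitative values are rounded half-away-from-zero to integers
by default (configurable as an `sprintf` format or a function), which is
how percentage labels are conventionally printed; qualitative labels pass
through verbatim; missing becomes the empty string. Text is centered in the
dot with an automatic black/white choice driven by fill luminance.

**Shape.** Qualitative levels map injectively onto an ordered symbol list
(circle, square, triangle, diamond, star, cross, hexagon); more levels than
symbols is a hard capacity error rather than a silent recycle, because
shape identity is the whole point of the channel. Quantitative shape — the
engine's distinctive glyph — rescales the value to a fraction in [0, 1]
over the shape domain and draws a filled circular sector of angle
2π·fraction over a light full-circle outline, a pie-like glyph that reads
directly as a percentage. The geometry is this package's concretization; an
alternative `symbol_series` style quantizes the fraction into five
equal-width bins for readers who prefer discrete steps.

All encoders are pure functions of their inputs, so identical tables and
specs always produce identical scenes.

## Type-dispatched factor analysis before clustering

Axis levels are reordered by agglomerative clustering of their factor
profiles. Because profiles may mix types, the profile matrix is first
embedded by the analysis appropriate to its columns:

* all quantitative → **PCA**: columns centered, scaled to unit sd (n−1
  denominator), zero-variance columns dropped with a warning; the SVD of
  the processed matrix gives row principal coordinates and eigenvalues
  `d²/(n−1)`, so the eigenvalue sum equals the processed matrix's total
  variance.
* all qualitative → **MCA**: correspondence analysis of the one-hot
  indicator matrix Z. With n rows, Q variables, J categories:
  P = Z/(nQ), row/column masses r and c, standardized residuals
  S = D_r^{−1/2}(P − rcᵀ)D_c^{−1/2}; the SVD of S yields eigenvalues
  summing to (J − Q)/Q (the trivial dimension is removed by the centering)
  and mass-standardized row principal coordinates.
* mixed → **FAMD**: quantitative columns standardized; each qualitative
  column expanded to indicators, each indicator divided by the square root
  of its category proportion (rescaled by √((n−1)/n)) and centered; then an
  unscaled PCA of the concatenation. The constants are chosen so that two
  identities hold *exactly*: with only quantitative columns FAMD equals
  scaled PCA (same eigenvalues and coordinates up to component signs), and
  total inertia equals `n_quant + (J − Q)`. With only qualitative columns
  the FAMD eigenvalues are exactly Q times the MCA eigenvalues — the two
  conventions weight the same spectrum differently, and the test suite
  asserts that exact proportionality.

Component signs are fixed by making each component's largest-magnitude
loading positive, so coordinates are reproducible across platforms.
Eigenvalues below 1e−12 are clamped to zero.

Missing values can only arise here through grid completion; they are
mean-imputed per profile column (quantitative) or become an own
`"(missing)"` category (qualitative), with a warning, because the factor
analyses need complete matrices and dropping levels would silently change
the plot.

## Clustering and dendrograms

Euclidean distances between embedding coordinates (all components by
default; `n_components` restricts to the leading ones) feed
`stats::hclust`. The default linkage is Ward (`ward.D2`, i.e. Ward's
criterion on Euclidean distances); complete, average and single linkage are
available. Merge ties are resolved by `hclust`'s internal convention and
leaf order is `hclust`'s ordering — on continuous data ties occur with
probability zero, and the suite verifies merge heights and topology against
a naive O(n³) Lance–Williams implementation for every linkage at all sizes
up to 8. By default the ordering uses all quantitative display factors when
any exist, else all factors; no optimal-leaf-ordering rotation is applied.
A single-level axis yields a degenerate dendrogram (no merges) with a
warning rather than an error, so scripted pipelines keep working on edge
cases. Dendrograms can be exported as Newick text for inspection.

## scRNA-seq summarization

The adaptor turns a genes × cells matrix plus a cell→cluster assignment
into the canonical dot-plot table:

* `Pct.exp` — 100 × (cells in the cluster with value > threshold)/(cluster
  size). The threshold defaults to 0 with a strict inequality: on counts or
  normalized values, "expressing" most naturally means "nonzero", and the
  cutoff is configurable for other conventions.
* `Avg.scaled.exp` — each gene z-scored across *all* cells (mean 0, sd 1,
  n−1 denominator), then averaged within each cluster. Scaling before
  averaging (rather than z-scoring cluster means) keeps the
  cluster-size-weighted mean at exactly 0 per gene, which the symmetric
  default color palette exploits. Zero-variance genes scale to 0 in every
  cluster, with a warning, instead of propagating NaN.

Values are used as given — normalization is upstream's job; per-gene or
per-(gene, cluster) annotations (marker flags, CNV status, a second
modality's percentages) join as extra columns and are broadcast per gene
where needed.

## Rendering and the plot object

`compose()` lays the grid, dendrograms (column tree above, row tree left,
each in a band 15% of the grid extent) and legends (stacked right, in
channel order size, color, shape, text) into a scene of primitive polygons,
segments and text anchors in one absolute coordinate system. Every symbol
is a polygon scaled so its *polygon* area equals the requested area, which
keeps size encoding exact across shapes.

Two serializations draw the same primitives:

* `render()` to SVG writes elements directly in a fixed order (background,
  dendrogram segments, glyphs row-major, axis labels, legends) with fixed
  two-decimal coordinates and no timestamps or generated ids — so identical
  input yields byte-identical files, which makes plots diffable and
  cacheable in pipelines;
* `as_ggplot()` wraps the primitives in a ggplot2 object that renders the
  same picture and accepts further user layers; PNG output rasterizes this
  handle at the requested dpi.

## The synthetic-data generator

`synthetic_expression()` emulates the structure the engine assumes
downstream of a clustering pipeline: a negative-binomial baseline with mean
1 and dispersion 0.5 (variance = μ + 0.5μ², giving ≈ 44% zeros, so
`Pct.exp` is informative rather than saturated), round-robin cluster
assignment, and a fraction `marker_rate = 0.3` of genes whose mean is
multiplied by `effect = 6` inside one assigned cluster. The defaults — 50
genes × 500 cells × 4 clusters — are the scale at which per-cluster marker
summaries are typically plotted. The generator reproduces exactly from its
seed.

What it does *not* emulate: library-size variation, gene-specific
dispersions, correlated modules, batch effects, ambient RNA, or multimodal
(ADT) noise. Passing tests therefore demonstrate the correctness of the
summarization arithmetic and the plotting laws on realistic sparsity — not
robustness to the full messiness of real single-cell data, whose
normalization is deliberately out of scope.

`synthetic_dot_table()` generates complete grids with uniform(0, 100)
quantitative factors and 2–4-level qualitative factors for the generic
table-model and rendering tests.

## Numerical choices and degenerate inputs

* Missing tokens on read: empty string, `NA`, `NaN` (case-insensitive);
  written back as `NA`.
* Duplicate (x, y) rows are an error, never aggregated silently.
* Degenerate size domain (hi = lo) gives mid-range areas with a warning.
* Zero-variance columns are dropped (PCA/FAMD) or zeroed (scaling) with
  warnings; all-degenerate input is an error.
* The checks in the test suite and the acceptance script run at modest
  problem sizes chosen to exercise every code path — 50 random tables for
  the inertia identities, all axis sizes up to 8 for the clustering oracle,
  20 seeded matrices up to 50 × 500 for the summarization oracle, and a 50
  gene × 500 cell × 4 cluster end-to-end plot.

## Known limitations

* No alpha channel and no continuous shape morphing beyond the sector
  glyph.
* Text extents are estimated from character counts (deterministic, but
  approximate for proportional fonts); very long labels may need a larger
  `cell_size`.
* The SVG and ggplot2 renderings share geometry but not font metrics, so
  they are visually equivalent rather than pixel-identical.
* No significance testing, bootstrap support, or cluster-number selection
  on the dendrograms; they order axes, nothing more.
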