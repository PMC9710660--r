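# Synthetic inputs emulating the structures the engine expects: a sparse
# count matrix with cluster-specific marker-gene blocks, and generic
# long-format dot tables with mixed factor types.

#' Simulate a clustered expression matrix with marker genes
#'
#' Counts are drawn from a negative-binomial baseline (mean 1, dispersion
#' 0.5, i.e. variance = mu + 0.5 mu^2), which yields realistic sparsity. A
#' fraction \code{marker_rate} of genes is made cluster-specific: within the
#' assigned cluster the gene's mean is multiplied by \code{effect}. Cells
#' are spread over clusters round-robin, so cluster sizes differ by at most
#' one. Fully reproducible from \code{seed}.
#'
#' @param n_genes,n_cells,n_clusters positive integers
#'   (\code{n_clusters <= n_cells}).
#' @param marker_rate fraction of genes made cluster-specific, in [0, 1].
#' @param effect fold change of a marker gene in its cluster (> 1).
#' @param seed integer random seed.
#' @return list with \code{matrix} (genes x cells), \code{clusters} (factor
#'   named by cell) and \code{markers} (data.frame gene, cluster).
#' @export
synthetic_expression <- function(n_genes = 50, n_cells = 500, n_clusters = 4,
                                 marker_rate = 0.3, effect = 6, seed = 1) {
  if (n_genes < 1 || n_cells < 1 || n_clusters < 1) {
    stop("n_genes, n_cells and n_clusters must be positive")
  }
  if (n_clusters > n_cells) stop("n_clusters must not exceed n_cells")
  if (marker_rate < 0 || marker_rate > 1) stop("marker_rate must be in [0, 1]")
  if (effect <= 1) stop("effect must be > 1")
  set.seed(as.integer(seed))

  genes <- sprintf("gene%02d", seq_len(n_genes))
  cells <- sprintf("cell%04d", seq_len(n_cells))
  cluster_levels <- sprintf("c%d", seq_len(n_clusters))
  clusters <- factor(rep_len(cluster_levels, n_cells), levels = cluster_levels)
  names(clusters) <- cells

  n_markers <- round(marker_rate * n_genes)
  marker_genes <- if (n_markers > 0) sample(genes, n_markers) else character(0)
  marker_cluster <- if (n_markers > 0) {
    sample(cluster_levels, n_markers, replace = TRUE)
  } else {
    character(0)
  }

  mu <- matrix(1, n_genes, n_cells, dimnames = list(genes, cells))
  for (i in seq_along(marker_genes)) {
    mu[marker_genes[i], clusters == marker_cluster[i]] <- effect
  }
  size <- 1 / 0.5  # NB size parameter for dispersion 0.5
  m <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = size),
              n_genes, n_cells, dimnames = list(genes, cells))
  list(matrix = m, clusters = clusters,
       markers = data.frame(gene = marker_genes, cluster = marker_cluster,
                            stringsAsFactors = FALSE))
}

#' Generate a random complete dot table
#'
#' Quantitative factors are uniform on [0, 100]; qualitative factors draw
#' from 2--4 labeled levels. The grid is complete and reproducible from
#' \code{seed}.
#'
#' @param n_x,n_y number of x and y levels.
#' @param n_quant,n_qual number of quantitative / qualitative display
#'   factors (1 to 4 in total).
#' @param seed integer random seed.
#' @return a [dot_table()] with \code{n_x * n_y} rows.
#' @export
synthetic_dot_table <- function(n_x = 4, n_y = 5, n_quant = 2, n_qual = 1,
                                seed = 1) {
  k <- n_quant + n_qual
  if (k < 1 || k > 4) {
    stop("n_quant + n_qual must be between 1 and 4")
  }
  if (n_x < 1 || n_y < 1) stop("n_x and n_y must be positive")
  set.seed(as.integer(seed))
  xl <- sprintf("x%02d", seq_len(n_x))
  yl <- sprintf("y%02d", seq_len(n_y))
  df <- data.frame(group = rep(xl, each = n_y), item = rep(yl, times = n_x),
                   stringsAsFactors = FALSE)
  kinds <- character(0)
  for (i in seq_len(n_quant)) {
    nm <- sprintf("quant%d", i)
    df[[nm]] <- round(stats::runif(nrow(df), 0, 100), 3L)
    kinds[nm] <- "quantitative"
  }
  for (i in seq_len(n_qual)) {
    nm <- sprintf("qual%d", i)
    n_lev <- sample(2:4, 1L)
    df[[nm]] <- sample(sprintf("lev%s%d", letters[i], seq_len(n_lev)),
                       nrow(df), replace = TRUE)
    kinds[nm] <- "qualitative"
  }
  dot_table(df, factor_kinds = kinds, x_levels = xl, y_levels = yl)
}

#' Write an expression fixture to disk
#'
#' Writes the matrix in MatrixMarket coordinate format with one-column gene
#' and cell name files, plus a (cell, cluster) CSV — the formats
#' [read_expression()] and [read_clusters()] read back.
#'
#' @param fixture result of [synthetic_expression()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_expression_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.txt"),
             cells = file.path(dir, "cells.txt"),
             clusters = file.path(dir, "clusters.csv"),
             markers = file.path(dir, "markers.csv"))
  Matrix::writeMM(Matrix::Matrix(fixture$matrix, sparse = TRUE),
                  paths[["matrix"]])
  writeLines(rownames(fixture$matrix), paths[["genes"]])
  writeLines(colnames(fixture$matrix), paths[["cells"]])
  utils::write.csv(
    data.frame(cell = names(fixture$clusters),
               cluster = as.character(fixture$clusters)),
    paths[["clusters"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(fixture$markers, paths[["markers"]],
                   row.names = FALSE, quote = FALSE)
  paths
}
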