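# Summaries of a gene x cell expression matrix per cell cluster:
# percent of expressing cells and mean of the per-gene z-score.

check_expression <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and cell colnames")
  }
  m
}

check_assignment <- function(m, clusters) {
  cells <- colnames(m)
  if (is.null(names(clusters))) {
    if (length(clusters) != ncol(m)) {
      stop("cluster labels must be named by cell or match the cell count")
    }
    names(clusters) <- cells
  }
  miss <- setdiff(cells, names(clusters))
  if (length(miss)) {
    stop("cells without a cluster label: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  out <- clusters[cells]
  if (!is.factor(out)) out <- factor(as.character(out), levels = unique(as.character(out)))
  out
}

check_genes <- function(m, genes) {
  if (is.null(genes)) return(rownames(m))
  miss <- setdiff(genes, rownames(m))
  if (length(miss)) {
    stop("unknown gene(s): ", paste(miss, collapse = ", "))
  }
  genes
}

#' Percentage of cells expressing each gene per cluster
#'
#' For each (gene, cluster) pair, the percentage (0--100) of cells in the
#' cluster whose expression value is strictly greater than \code{threshold}.
#'
#' @param m genes x cells matrix (dense or \pkg{Matrix} sparse) with
#'   dimnames; values are used as given.
#' @param clusters cluster label per cell, named by cell (or in matrix
#'   column order). Factor level order sets the cluster column order.
#' @param genes genes to summarize (default all); unknown genes error.
#' @param threshold expression cutoff; a cell "expresses" when value >
#'   threshold. Default 0.
#' @return numeric matrix, genes x clusters, values in [0, 100].
#' @export
pct_expressed <- function(m, clusters, genes = NULL, threshold = 0) {
  m <- check_expression(m)
  cl <- check_assignment(m, clusters)
  genes <- check_genes(m, genes)
  lev <- levels(cl)
  sizes <- table(cl)
  if (any(sizes == 0L)) {
    stop("empty cluster(s): ", paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  out <- matrix(NA_real_, length(genes), length(lev), dimnames = list(genes, lev))
  for (k in lev) {
    sub <- m[genes, cl == k, drop = FALSE]
    out[, k] <- 100 * Matrix::rowSums(sub > threshold) / ncol(sub)
  }
  out
}

#' Mean scaled expression per cluster
#'
#' Each gene is z-scored across all cells (mean 0, sd 1, sd with n-1
#' denominator); the z-scores are then averaged within each cluster. The
#' cluster-size-weighted mean over clusters is therefore 0 for every gene.
#' Genes with zero variance get 0 in every cluster, with a warning.
#'
#' @inheritParams pct_expressed
#' @return numeric matrix, genes x clusters.
#' @export
mean_scaled_expression <- function(m, clusters, genes = NULL) {
  m <- check_expression(m)
  cl <- check_assignment(m, clusters)
  genes <- check_genes(m, genes)
  if (ncol(m) < 2L) stop("at least 2 cells are required to scale expression")
  x <- as.matrix(m[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning("zero-variance gene(s) scaled to 0: ",
            paste(genes[flat], collapse = ", "))
    sdv[flat] <- 1
  }
  z <- (x - mu) / sdv
  z[flat, ] <- 0
  lev <- levels(cl)
  out <- matrix(NA_real_, length(genes), length(lev), dimnames = list(genes, lev))
  for (k in lev) {
    out[, k] <- rowMeans(z[, cl == k, drop = FALSE])
  }
  out
}

#' Build a dot table of per-cluster gene summaries
#'
#' Produces the canonical scRNA-seq dot-plot input: one row per
#' (cluster, gene) with the percentage of expressing cells (`Pct.exp`) and
#' the mean scaled expression (`Avg.scaled.exp`), plus optional extra
#' annotation columns. Clusters become the x axis, genes the y axis.
#'
#' @inheritParams pct_expressed
#' @param extra optional named list of annotations. Each element is either a
#'   vector named by gene (broadcast to all of that gene's rows) or a
#'   genes x clusters matrix with dimnames. Kinds are inferred per column.
#' @return a [dot_table()] with `|genes| * |clusters|` rows.
#' @export
build_dot_table <- function(m, clusters, genes = NULL, extra = NULL,
                            threshold = 0) {
  m <- check_expression(m)
  cl <- check_assignment(m, clusters)
  genes <- check_genes(m, genes)
  pct <- pct_expressed(m, cl, genes, threshold)
  mse <- mean_scaled_expression(m, cl, genes)
  lev <- levels(cl)
  df <- data.frame(
    Cluster = rep(lev, each = length(genes)),
    Gene = rep(genes, times = length(lev)),
    stringsAsFactors = FALSE
  )
  ij <- cbind(match(df$Gene, genes), match(df$Cluster, lev))
  df$Pct.exp <- pct[ij]
  df$Avg.scaled.exp <- mse[ij]
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stop("'extra' must be a fully named list")
    }
    for (nm in names(extra)) {
      e <- extra[[nm]]
      if (is.matrix(e)) {
        bad <- setdiff(genes, rownames(e))
        if (length(bad)) stop(sprintf("extra '%s' lacks gene(s): %s", nm,
                                      paste(bad, collapse = ", ")))
        bad <- setdiff(lev, colnames(e))
        if (length(bad)) stop(sprintf("extra '%s' lacks cluster(s): %s", nm,
                                      paste(bad, collapse = ", ")))
        df[[nm]] <- e[cbind(match(df$Gene, rownames(e)),
                            match(df$Cluster, colnames(e)))]
      } else {
        bad <- setdiff(genes, names(e))
        if (length(bad)) stop(sprintf("extra '%s' lacks gene(s): %s", nm,
                                      paste(bad, collapse = ", ")))
        df[[nm]] <- e[df$Gene]
      }
    }
  }
  dot_table(df, x_levels = lev, y_levels = genes)
}

#' Read an expression matrix
#'
#' Either MatrixMarket coordinate format plus two one-column text files with
#' gene and cell names, or a dense CSV with gene rows and cell columns
#' (first column = gene names, header = cell names).
#'
#' @param path `.mtx` file or dense CSV path.
#' @param genes_path,cells_path name files accompanying an `.mtx` matrix.
#' @return genes x cells matrix (sparse for MTX input).
#' @export
read_expression <- function(path, genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("MTX input requires genes_path and cells_path name files")
    }
    m <- Matrix::readMM(path)
    g <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(g) || ncol(m) != length(cells)) {
      stop("matrix dimensions do not match the name files")
    }
    dimnames(m) <- list(g, cells)
    m
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    m
  }
}

#' Read a cell-to-cluster assignment
#'
#' Two-column CSV (cell, cluster), header optional but recommended.
#'
#' @param path CSV path.
#' @return factor of cluster labels named by cell, levels in first
#'   appearance order.
#' @export
read_clusters <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("cluster file needs two columns (cell, cluster)")
  lab <- as.character(df[[2L]])
  stats::setNames(factor(lab, levels = unique(lab)), as.character(df[[1L]]))
}
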