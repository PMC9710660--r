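# Axis reordering: pivot the chosen factors wide along one axis, embed the
# level profiles with the type-appropriate factor analysis, then cluster the
# embedding coordinates hierarchically.

LINKAGES <- c("ward", "complete", "average", "single")

new_axis_dendrogram <- function(hc, labels, axis, linkage) {
  if (is.null(hc)) {
    merges <- matrix(numeric(0), 0L, 2L)
    heights <- numeric(0)
    order <- labels
  } else {
    merges <- hc$merge
    heights <- hc$height
    order <- hc$labels[hc$order]
  }
  structure(list(merges = merges, heights = heights, leaf_order = order,
                 labels = labels, axis = axis, linkage = linkage,
                 hclust = hc),
            class = "axis_dendrogram")
}

#' @export
print.axis_dendrogram <- function(x, ...) {
  cat(sprintf("<axis_dendrogram> axis=%s, %d leaves, %d merges (%s linkage)\n",
              x$axis, length(x$labels), nrow(x$merges), x$linkage))
  cat("leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.hclust.axis_dendrogram <- function(x, ...) {
  if (is.null(x$hclust)) stop("degenerate dendrogram (single leaf) has no hclust form")
  x$hclust
}

#' Order the levels of one axis by hierarchical clustering
#'
#' Each chosen display factor is pivoted wide along the axis (one profile
#' per axis level); the concatenated profiles are embedded by PCA (all
#' quantitative), MCA (all qualitative) or FAMD (mixed); axis levels are
#' then clustered agglomeratively on the Euclidean distances between their
#' embedding coordinates.
#'
#' Missing values (from grid completion) are mean-imputed per profile column
#' for quantitative factors and become an own \code{"(missing)"} category
#' for qualitative factors, with a warning.
#'
#' @param table a [dot_table()].
#' @param axis \code{"x"} or \code{"y"}: which axis to reorder.
#' @param factors display factors driving the ordering; default: all
#'   quantitative factors if any exist, else all factors.
#' @param linkage \code{"ward"} (Ward on Euclidean distances, the default),
#'   \code{"complete"}, \code{"average"} or \code{"single"}.
#' @param n_components number of leading embedding components to use
#'   (default all).
#' @return an \code{axis_dendrogram}: merge table, heights, leaf order, and
#'   the underlying [stats::hclust()] object. A single-level axis yields a
#'   degenerate dendrogram with no merges (with a warning).
#' @export
order_axis <- function(table, axis = c("x", "y"), factors = NULL,
                       linkage = LINKAGES, n_components = NULL) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  kinds <- factor_kinds(table)
  if (is.null(factors)) {
    factors <- if (any(kinds == "quantitative")) {
      names(kinds)[kinds == "quantitative"]
    } else {
      names(kinds)
    }
  }
  bad <- setdiff(factors, names(kinds))
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
  if (!length(factors)) stop("at least one factor is required to order an axis")

  labels <- if (axis == "x") x_levels(table) else y_levels(table)
  if (length(labels) < 2L) {
    warning("axis '", axis, "' has a single level; returning a degenerate dendrogram")
    return(new_axis_dendrogram(NULL, labels, axis, linkage))
  }

  table <- complete_grid(table)
  quant <- list()
  qual <- list()
  for (f in factors) {
    wide <- pivot_wide(table, f, axis)
    if (kinds[[f]] == "quantitative") {
      if (anyNA(wide)) {
        warning(sprintf("mean-imputing missing values of '%s' for ordering", f))
        for (j in seq_len(ncol(wide))) {
          mis <- is.na(wide[, j])
          if (any(mis)) wide[mis, j] <- mean(wide[!mis, j])
        }
        wide[is.na(wide)] <- 0  # all-missing profile column
      }
      colnames(wide) <- paste(f, colnames(wide), sep = ".")
      quant[[f]] <- wide
    } else {
      if (anyNA(wide)) {
        warning(sprintf("treating missing values of '%s' as an own category for ordering", f))
        wide[is.na(wide)] <- "(missing)"
      }
      df <- as.data.frame(wide, stringsAsFactors = FALSE)
      names(df) <- paste(f, colnames(wide), sep = ".")
      qual[[f]] <- df
    }
  }

  emb <- if (length(quant) && !length(qual)) {
    pca_embed(do.call(cbind, quant), scale = TRUE)
  } else if (!length(quant) && length(qual)) {
    mca_embed(do.call(cbind, qual))
  } else {
    q_df <- as.data.frame(do.call(cbind, quant))
    c_df <- do.call(cbind, qual)
    famd_embed(cbind(q_df, c_df),
               kinds = c(rep("quantitative", ncol(q_df)),
                         rep("qualitative", ncol(c_df))))
  }

  co <- emb$coordinates
  if (!is.null(n_components)) {
    co <- co[, seq_len(min(n_components, ncol(co))), drop = FALSE]
  }
  rownames(co) <- labels
  d <- stats::dist(co)
  hc <- stats::hclust(d, method = switch(linkage,
                                         ward = "ward.D2",
                                         complete = "complete",
                                         average = "average",
                                         single = "single"))
  new_axis_dendrogram(hc, labels, axis, linkage)
}

#' Export a dendrogram as Newick text
#'
#' @param dend an \code{axis_dendrogram} from [order_axis()].
#' @return a single Newick string with branch lengths from merge heights.
#' @export
as_newick <- function(dend) {
  stopifnot(inherits(dend, "axis_dendrogram"))
  if (is.null(dend$hclust)) {
    return(paste0("(", dend$labels, ");"))
  }
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(dend$hclust))
}
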