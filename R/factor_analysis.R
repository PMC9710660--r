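# Type-dispatched factor analyses used before axis clustering:
# PCA for quantitative columns, MCA for qualitative columns, FAMD for a mix.
# All three share one convention: component signs are fixed so that each
# component's largest-magnitude loading is positive, and eigenvalues below
# 1e-12 are clamped to 0.

new_embedding <- function(coordinates, eigenvalues, method, row_labels) {
  eigenvalues <- ifelse(eigenvalues < 1e-12, 0, eigenvalues)
  stopifnot(!is.unsorted(rev(eigenvalues)))
  structure(list(row_labels = row_labels,
                 coordinates = coordinates,
                 eigenvalues = eigenvalues,
                 method = method),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> method=%s, %d rows, %d components\n",
              x$method, nrow(x$coordinates), length(x$eigenvalues)))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4L), collapse = " "), "\n")
  invisible(x)
}

# Flip each component so its largest |loading| is positive; u/v are the SVD
# factors, coordinates derive from u so both must flip together.
fix_signs <- function(u, v, d) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  list(u = u, v = v, d = d)
}

#' Principal component analysis of a quantitative matrix
#'
#' Columns are centered (and scaled to unit sd, n-1 denominator, when
#' \code{scale = TRUE}); zero-variance columns are dropped with a warning.
#' The SVD of the processed matrix gives row principal coordinates and
#' eigenvalues (squared singular values divided by n-1), so the eigenvalue
#' sum equals the total variance of the processed matrix.
#'
#' @param x numeric matrix or data.frame, rows = observations.
#' @param scale scale columns to unit variance (default TRUE).
#' @return an \code{embedding} (row coordinates, eigenvalues, method).
#' @export
pca_embed <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  mode(x) <- "double"
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows")
  if (anyNA(x)) stop("PCA input must not contain missing values")
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  sdv <- apply(x, 2L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all columns have zero variance")
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
    sdv <- sdv[keep]
  }
  x <- sweep(x, 2L, colMeans(x))
  if (scale) x <- sweep(x, 2L, sdv, "/")
  sv <- svd(x)
  sv <- fix_signs(sv$u, sv$v, sv$d)
  n <- nrow(x)
  coords <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(coords) <- labels
  new_embedding(coords, sv$d^2 / (n - 1), "pca", labels)
}

# One-hot indicator matrix of a character/factor data.frame; columns named
# <var>=<level>, with the per-column category proportions attached.
indicator_matrix <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  blocks <- lapply(names(x), function(nm) {
    f <- factor(as.character(x[[nm]]))
    z <- stats::model.matrix(~ f - 1)
    colnames(z) <- paste(nm, levels(f), sep = "=")
    z
  })
  z <- do.call(cbind, blocks)
  attr(z, "n_levels") <- vapply(x, function(col) length(unique(as.character(col))), 1L)
  z
}

#' Multiple correspondence analysis of qualitative columns
#'
#' Correspondence analysis of the one-hot indicator matrix: with n rows, Q
#' variables and J categories in total, the correspondence matrix is
#' P = Z/(nQ); the SVD of the standardized residual
#' S = Dr^{-1/2} (P - r c') Dc^{-1/2} yields eigenvalues (squared singular
#' values, trivial dimension already removed by the centering) summing to
#' (J - Q)/Q, and mass-standardized row principal coordinates. Columns with
#' a single category carry no inertia and are dropped with a warning.
#'
#' @param x data.frame or character matrix of qualitative columns.
#' @return an \code{embedding}.
#' @export
mca_embed <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) < 2L) stop("MCA needs at least 2 rows")
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  n_lev <- vapply(x, function(col) length(unique(as.character(col))), 1L)
  keep <- n_lev > 1L
  if (!any(keep)) stop("all qualitative columns have a single category")
  if (!all(keep)) {
    warning("dropping single-category column(s): ",
            paste(names(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  z <- indicator_matrix(x)
  n <- nrow(z); q <- ncol(x); j <- ncol(z)
  p <- z / (n * q)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- (p - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  sv <- svd(s)
  # rank is at most min(n - 1, J - Q): drop numerically-zero dimensions
  rank <- min(n - 1L, j - q)
  d <- sv$d[seq_len(rank)]
  u <- sv$u[, seq_len(rank), drop = FALSE]
  v <- sv$v[, seq_len(rank), drop = FALSE]
  sv <- fix_signs(u, v, d)
  coords <- (sv$u / sqrt(r)) %*% diag(sv$d, length(sv$d))
  rownames(coords) <- labels
  new_embedding(coords, sv$d^2, "mca", labels)
}

#' Factor analysis of mixed data
#'
#' Quantitative columns are standardized (mean 0, unit sd); each qualitative
#' column is expanded to indicators, each indicator weighted by
#' 1/sqrt(category proportion) and centered. An unscaled PCA of the
#' concatenation balances the two kinds: each quantitative column
#' contributes inertia 1 and each qualitative column (levels - 1), so with
#' all-quantitative input the result equals \code{pca_embed(x, scale=TRUE)}
#' and with all-qualitative input the eigenvalues equal Q times the MCA
#' eigenvalues.
#'
#' @param x data.frame of mixed columns.
#' @param kinds character vector ("quantitative"/"qualitative") per column;
#'   inferred when NULL.
#' @return an \code{embedding}.
#' @export
famd_embed <- function(x, kinds = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) < 2L) stop("FAMD needs at least 2 rows")
  if (ncol(x) < 1L) stop("FAMD needs at least 1 column")
  if (is.null(kinds)) {
    kinds <- vapply(x, function(col) {
      if (is.numeric(col)) "quantitative" else infer_factor_kind(as.character(col))
    }, "")
  }
  if (length(kinds) != ncol(x)) stop("one kind per column is required")
  if (!all(kinds %in% c("quantitative", "qualitative"))) {
    stop("kinds must be 'quantitative' or 'qualitative'")
  }
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  n <- nrow(x)

  blocks <- list()
  for (i in seq_along(x)) {
    nm <- names(x)[i]
    if (kinds[i] == "quantitative") {
      col <- as.numeric(x[[i]])
      s <- stats::sd(col)
      if (s == 0) {
        warning("dropping zero-variance column: ", nm)
        next
      }
      blocks[[nm]] <- matrix((col - mean(col)) / s, ncol = 1L,
                             dimnames = list(NULL, nm))
    } else {
      lev <- unique(as.character(x[[i]]))
      if (length(lev) < 2L) {
        warning("dropping single-category column: ", nm)
        next
      }
      z <- indicator_matrix(x[i])
      prop <- colMeans(z)
      # 1/sqrt(proportion) weight, rescaled so the n-1 variance of each
      # weighted indicator is exactly (1 - proportion); centered below
      w <- sweep(z, 2L, sqrt(prop / ((n - 1) / n)), "/")
      blocks[[nm]] <- sweep(w, 2L, colMeans(w))
    }
  }
  if (!length(blocks)) stop("no usable columns after dropping degenerate ones")
  w <- do.call(cbind, blocks)
  w <- sweep(w, 2L, colMeans(w))
  sv <- svd(w)
  rank <- sum(sv$d^2 / (n - 1) > 1e-12)
  rank <- max(rank, 1L)
  sv <- fix_signs(sv$u[, seq_len(rank), drop = FALSE],
                  sv$v[, seq_len(rank), drop = FALSE],
                  sv$d[seq_len(rank)])
  coords <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(coords) <- labels
  new_embedding(coords, sv$d^2 / (n - 1), "famd", labels)
}
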