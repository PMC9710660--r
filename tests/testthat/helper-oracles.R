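# Independent brute-force oracles used across the suite. These deliberately
# use explicit loops / naive algorithms and never call the package code
# paths they check.

# naive O(n^3) agglomerative clustering via Lance-Williams updates.
# Returns merge heights (non-decreasing) and, per merge, the sorted set of
# leaf labels of the newly formed cluster (a tree-topology fingerprint that
# does not depend on within-row merge ordering conventions).
naive_agglomerate <- function(coords, linkage) {
  dm <- as.matrix(stats::dist(coords))
  n <- nrow(dm)
  labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  squared <- linkage == "ward"
  if (squared) dm <- dm^2
  members <- lapply(seq_len(n), function(i) labels[i])
  sizes <- rep(1, n)
  heights <- numeric(n - 1L)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    m <- nrow(dm)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (dm[i, j] < best) { best <- dm[i, j]; bi <- i; bj <- j }
      }
    }
    heights[k] <- if (squared) sqrt(best) else best
    ni <- sizes[bi]; nj <- sizes[bj]
    newd <- numeric(m)
    for (l in seq_len(m)) {
      if (l == bi || l == bj) next
      nl <- sizes[l]
      newd[l] <- switch(linkage,
        single = min(dm[bi, l], dm[bj, l]),
        complete = max(dm[bi, l], dm[bj, l]),
        average = (ni * dm[bi, l] + nj * dm[bj, l]) / (ni + nj),
        ward = ((ni + nl) * dm[bi, l] + (nj + nl) * dm[bj, l] -
                  nl * dm[bi, bj]) / (ni + nj + nl))
    }
    sets[[k]] <- sort(c(members[[bi]], members[[bj]]))
    keep <- setdiff(seq_len(m), c(bi, bj))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    members <- c(members[keep], list(sets[[k]]))
    sizes <- c(sizes[keep], ni + nj)
    dm <- dm2
  }
  list(heights = heights, sets = sets)
}

# leaf sets of each merge of an axis_dendrogram (same fingerprint)
dend_leafsets <- function(dend) {
  m <- dend$merges
  labels <- dend$labels
  sets <- vector("list", nrow(m))
  get <- function(id) if (id < 0) labels[-id] else sets[[id]]
  for (k in seq_len(nrow(m))) {
    sets[[k]] <- sort(c(get(m[k, 1L]), get(m[k, 2L])))
  }
  sets
}

# brute-force per-cluster summaries with explicit loops
brute_pct <- function(m, clusters, threshold = 0) {
  genes <- rownames(m); lev <- levels(clusters)
  out <- matrix(NA_real_, length(genes), length(lev),
                dimnames = list(genes, lev))
  for (g in genes) {
    for (k in lev) {
      cells <- names(clusters)[clusters == k]
      cnt <- 0L
      for (cell in cells) if (m[g, cell] > threshold) cnt <- cnt + 1L
      out[g, k] <- 100 * cnt / length(cells)
    }
  }
  out
}

brute_mse <- function(m, clusters) {
  genes <- rownames(m); lev <- levels(clusters)
  out <- matrix(NA_real_, length(genes), length(lev),
                dimnames = list(genes, lev))
  for (g in genes) {
    v <- as.numeric(m[g, ])
    mu <- sum(v) / length(v)
    s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    z <- if (s == 0) rep(0, length(v)) else (v - mu) / s
    names(z) <- colnames(m)
    for (k in lev) {
      cells <- names(clusters)[clusters == k]
      out[g, k] <- mean(z[cells])
    }
  }
  out
}

# brute-force MCA total inertia: trace of S'S of the indicator CA, built
# with explicit loops
brute_mca_inertia <- function(df) {
  n <- nrow(df)
  cats <- list()
  for (nm in names(df)) {
    for (lev in unique(as.character(df[[nm]]))) {
      cats[[paste(nm, lev)]] <- as.numeric(as.character(df[[nm]]) == lev)
    }
  }
  z <- do.call(cbind, cats)
  q <- ncol(df)
  p <- z / (n * q)
  r <- rowSums(p); cc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      s <- s + (p[i, j] - r[i] * cc[j])^2 / (r[i] * cc[j])
    }
  }
  unname(s)
}

# small in-memory dot table used by several files
tiny_table <- function() {
  dot_table(data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g3"),
    cl = c("c1", "c2", "c1", "c2", "c1", "c2"),
    pct = c(10, 90, 50, 60, 0, 100),
    expr = c(-1.2, 1.2, 0, 0.4, -2, 2),
    flag = c("m", "m", "o", "o", "m", "o"),
    stringsAsFactors = FALSE))
}
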