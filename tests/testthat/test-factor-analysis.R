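test_that("PCA recovers the hand-computed 2x2 eigendecomposition", {
  # rows (0,0) and (2,2): covariance [[2,2],[2,2]], eigenvalues 4 and 0
  e <- pca_embed(rbind(c(0, 0), c(2, 2)), scale = FALSE)
  expect_equal(e$eigenvalues, c(4, 0), tolerance = 1e-12)
  expect_equal(unname(abs(e$coordinates[, 1L])), c(sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("PCA eigenvalue sum equals processed-matrix total variance", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(6 * 4), 6, 4)
    e <- pca_embed(x, scale = FALSE)
    expect_equal(sum(e$eigenvalues), sum(apply(x, 2, var)), tolerance = 1e-10)
    es <- pca_embed(x, scale = TRUE)
    expect_equal(sum(es$eigenvalues), 4, tolerance = 1e-10)
    # agreement with the stock implementation up to component signs
    pr <- prcomp(x, scale. = TRUE)
    expect_equal(abs(unname(es$coordinates)), abs(unname(pr$x)),
                 tolerance = 1e-8)
    expect_equal(es$eigenvalues, unname(pr$sdev^2), tolerance = 1e-10)
  }
})

test_that("PCA drops constant columns and rejects degenerate input", {
  set.seed(1)
  x <- matrix(rnorm(20), 5, 4)
  e0 <- pca_embed(x)
  expect_warning(e1 <- pca_embed(cbind(x, k = 7)), "zero-variance")
  expect_equal(e1$eigenvalues, e0$eigenvalues, tolerance = 1e-12)
  expect_error(pca_embed(x[1, , drop = FALSE]), "at least 2 rows")
  expect_error(suppressWarnings(pca_embed(matrix(1, 4, 2))), "zero variance")
  expect_error(pca_embed(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("MCA eigenvalues satisfy the (J-Q)/Q inertia identity", {
  # balanced 2x2 design: J=4, Q=2, total inertia 1
  df <- data.frame(a = c("u", "u", "v", "v"), b = c("p", "q", "p", "q"))
  e <- mca_embed(df)
  expect_equal(sum(e$eigenvalues), 1, tolerance = 1e-10)
  # two perfectly associated columns: leading eigenvalue 1
  df2 <- data.frame(a = c("u", "u", "v", "v"), b = c("p", "p", "q", "q"))
  e2 <- mca_embed(df2)
  expect_equal(e2$eigenvalues[1L], 1, tolerance = 1e-10)
  # arbitrary tables vs brute-force indicator-matrix CA inertia
  for (seed in 1:5) {
    set.seed(seed)
    df3 <- data.frame(
      a = sample(letters[1:3], 12, replace = TRUE),
      b = sample(c("x", "y"), 12, replace = TRUE),
      c = sample(c("p", "q", "r", "s"), 12, replace = TRUE))
    j <- sum(vapply(df3, function(col) length(unique(col)), 1L))
    e3 <- mca_embed(df3)
    expect_equal(sum(e3$eigenvalues), (j - 3) / 3, tolerance = 1e-10)
    expect_equal(sum(e3$eigenvalues), brute_mca_inertia(df3), tolerance = 1e-10)
  }
})

test_that("MCA drops single-category columns and keeps the identity on the rest", {
  df <- data.frame(a = c("u", "u", "v", "v"), konst = rep("z", 4),
                   b = c("p", "q", "p", "q"))
  expect_warning(e <- mca_embed(df), "konst")
  expect_equal(sum(e$eigenvalues), 1, tolerance = 1e-10)
  expect_error(suppressWarnings(mca_embed(data.frame(a = rep("z", 4)))),
               "single category")
})

test_that("FAMD reduces to scaled PCA when all columns are quantitative", {
  set.seed(2)
  x <- as.data.frame(matrix(rnorm(7 * 3), 7, 3))
  f <- famd_embed(x, kinds = rep("quantitative", 3))
  p <- pca_embed(as.matrix(x), scale = TRUE)
  expect_equal(f$eigenvalues, p$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(unname(f$coordinates)), abs(unname(p$coordinates)),
               tolerance = 1e-8)
})

test_that("FAMD on qualitative columns is MCA up to the factor Q", {
  df <- data.frame(a = c("u", "u", "v", "v"), b = c("p", "q", "q", "p"))
  f <- famd_embed(df, kinds = rep("qualitative", 2))
  m <- mca_embed(df)
  q <- 2
  nz <- m$eigenvalues > 1e-12
  expect_equal(f$eigenvalues[seq_len(sum(nz))], q * m$eigenvalues[nz],
               tolerance = 1e-10)
})

test_that("FAMD total inertia is n_quantitative + (J - Q)", {
  # 1 quantitative + 1 binary qualitative: 1 + (2 - 1) = 2
  set.seed(3)
  df <- data.frame(q = rnorm(6), c = rep(c("a", "b"), 3))
  f <- famd_embed(df, kinds = c("quantitative", "qualitative"))
  expect_equal(sum(f$eigenvalues), 2, tolerance = 1e-10)
  # larger mixed case: 2 quantitative + (3-1) + (2-1)
  df2 <- data.frame(q1 = rnorm(9), q2 = runif(9),
                    c1 = sample(c("a", "b", "c"), 9, replace = TRUE),
                    c2 = rep(c("x", "y", "x"), 3))
  f2 <- famd_embed(df2, kinds = c("quantitative", "quantitative",
                                  "qualitative", "qualitative"))
  expect_equal(sum(f2$eigenvalues), 2 + 2 + 1, tolerance = 1e-10)
})

test_that("eigenvalues are non-negative and non-increasing for all methods", {
  set.seed(4)
  embeddings <- list(
    pca_embed(matrix(rnorm(30), 6, 5)),
    mca_embed(data.frame(a = sample(letters[1:3], 10, TRUE),
                         b = sample(letters[4:5], 10, TRUE))),
    famd_embed(data.frame(q = rnorm(8),
                          c = sample(c("u", "v"), 8, TRUE)),
               kinds = c("quantitative", "qualitative")))
  for (e in embeddings) {
    expect_true(all(e$eigenvalues >= 0))
    expect_true(all(diff(e$eigenvalues) <= 1e-12))
    expect_equal(ncol(e$coordinates), length(e$eigenvalues))
  }
})
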