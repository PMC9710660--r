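test_that("glyph count follows the counting law", {
  tab <- tiny_table()
  spec <- channel_spec(size = "pct", color = "expr")
  sc <- compose(tab, spec)
  expect_equal(nrow(sc$glyphs), 6L)           # complete 3x2 grid
  expect_equal(length(sc$legend_blocks), 2L)  # size + color

  # size bound: combinations with missing size values are omitted
  tab2 <- dot_table(data.frame(x = c("a", "a", "b"), y = c("u", "v", "u"),
                               pct = c(10, NA, 30)))
  sc2 <- compose(tab2, channel_spec(size = "pct"))
  expect_equal(nrow(sc2$glyphs), 2L)
  # size unbound: every combination drawn (incl. grid-completed missing)
  sc3 <- compose(tab2, channel_spec(color = "pct"))
  expect_equal(nrow(sc3$glyphs), 4L)
  # indices within grid bounds
  for (sc_i in list(sc, sc2, sc3)) {
    expect_true(all(sc_i$glyphs$x_index >= 1 &
                      sc_i$glyphs$x_index <= length(sc_i$x_levels)))
    expect_true(all(sc_i$glyphs$y_index >= 1 &
                      sc_i$glyphs$y_index <= length(sc_i$y_levels)))
  }
})

test_that("axis orders follow dendrogram leaf orders", {
  tab <- synthetic_dot_table(n_x = 6, n_y = 5, n_quant = 2, n_qual = 0,
                             seed = 17)
  spec <- channel_spec(size = "quant1", color = "quant2")
  rd <- order_axis(tab, "y")
  cd <- order_axis(tab, "x")
  sc <- compose(tab, spec, row_dend = rd, col_dend = cd)
  expect_identical(sc$x_levels, cd$leaf_order)
  expect_identical(sc$y_levels, rd$leaf_order)
  # without dendrograms: table level order
  sc0 <- compose(tab, spec)
  expect_identical(sc0$x_levels, x_levels(tab))
  expect_identical(sc0$y_levels, y_levels(tab))
})

test_that("a dendrogram over the wrong labels is a consistency error", {
  tab <- synthetic_dot_table(n_x = 4, n_y = 3, n_quant = 1, n_qual = 0,
                             seed = 2)
  other <- synthetic_dot_table(n_x = 5, n_y = 3, n_quant = 1, n_qual = 0,
                               seed = 2)
  cd <- order_axis(other, "x")
  expect_error(compose(tab, channel_spec(size = "quant1"), col_dend = cd),
               "do not match")
})

test_that("legends are generated per bound channel and are suppressible", {
  tab <- tiny_table()
  spec <- channel_spec(size = "pct", color = "expr", text = "pct",
                       shape = "flag")
  sc <- compose(tab, spec)
  types <- vapply(sc$legend_blocks, `[[`, "", "type")
  expect_identical(types, c("size_dots", "color_bar", "shape_symbols",
                            "text_note"))
  # size legend: reference dots at domain lo/mid/max
  size_blk <- sc$legend_blocks[[1L]]
  expect_equal(size_blk$entries$value, c(0, 50, 100))
  # qualitative color -> swatches in level order
  sc_q <- compose(tab, channel_spec(color = "flag"))
  blk <- sc_q$legend_blocks[[1L]]
  expect_identical(blk$type, "color_swatches")
  expect_identical(blk$entries$level, c("m", "o"))
  # suppression
  sc_no <- compose(tab, spec, legends = c("color", "shape"))
  expect_identical(vapply(sc_no$legend_blocks, `[[`, "", "channel"),
                   c("color", "shape"))
  expect_length(compose(tab, spec, legends = FALSE)$legend_blocks, 0L)
})

test_that("quantitative shape legends show reference sectors at 0, 1/2 and 1", {
  tab <- tiny_table()
  sc <- compose(tab, channel_spec(shape = "pct"))
  blk <- sc$legend_blocks[[1L]]
  expect_identical(blk$type, "shape_fractions")
  expect_equal(blk$entries$fraction, c(0, 0.5, 1))
  expect_equal(blk$entries$value, c(0, 50, 100))
})

test_that("split_columns doubles the x levels preserving adjacency", {
  df <- expand.grid(pair = c("TAM|TP1", "TAM|TP2", "B|T", "NK|DC"),
                    gene = c("CD74_MIF", "HLA_A"), stringsAsFactors = FALSE)
  set.seed(4)
  df$left <- runif(nrow(df), 0, 10)
  df$right <- runif(nrow(df), 0, 10)
  df$sig <- sample(c("yes", "no"), nrow(df), replace = TRUE)
  tab <- dot_table(df)
  sp <- split_columns(tab, "left", "right")
  expect_equal(length(x_levels(sp)), 8L)
  expect_equal(nrow(sp), 2L * nrow(tab))
  xl <- x_levels(sp)
  expect_identical(xl[1:2], c("TAM|TP1:TAM", "TAM|TP1:TP1"))
  # left sub-column carries the left factor's values
  expect_equal(sp$left_right[sp[[1L]] == "TAM|TP1:TAM"],
               df$left[df$pair == "TAM|TP1"])
  expect_equal(sp$left_right[sp[[1L]] == "TAM|TP1:TP1"],
               df$right[df$pair == "TAM|TP1"])
  # shared attribute carried on both sides by default
  expect_identical(factor_kinds(sp)[["sig"]], "qualitative")
  expect_false(anyNA(sp$sig))
  # carry = left leaves the right side missing
  sp_l <- split_columns(tab, "left", "right", carry = "left")
  right_rows <- grepl(":TP1$|:TP2$|:T$|:DC$", sp_l[[1L]])
  expect_true(all(is.na(sp_l$sig[right_rows])))
  # equal left/right values render identically on both sides
  df_eq <- df; df_eq$right <- df_eq$left
  sp_eq <- split_columns(dot_table(df_eq), "left", "right")
  m <- pivot_wide(sp_eq, "left_right", "x")
  expect_equal(m[seq(1, 7, by = 2), ], m[seq(2, 8, by = 2), ],
               ignore_attr = TRUE)
})

test_that("split_columns validates the separator and factor types", {
  tab <- dot_table(data.frame(x = c("A|B", "plain"), y = "u", l = 1:2, r = 3:4))
  expect_error(split_columns(tab, "l", "r"), "plain")
  tab2 <- dot_table(data.frame(x = "A|B|C", y = "u", l = 1, r = 2))
  expect_error(split_columns(tab2, "l", "r"), "exactly once")
  tab3 <- tiny_table()
  expect_error(split_columns(tab3, "pct", "flag"), "quantitative")
})
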