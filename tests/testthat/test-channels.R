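test_that("channel specs validate structure and type compatibility", {
  expect_error(channel_spec(), "at least one channel")
  expect_error(channel_spec(size = "v", size_range = c(5, 2)), "size_range")
  spec <- channel_spec(size = "pct", color = "expr", shape = "flag")
  tab <- tiny_table()
  expect_invisible(validate_channels(spec, tab))
  # Fig-1B-style rule: size takes quantitative factors only
  expect_error(validate_channels(channel_spec(size = "flag"), tab),
               "size channel requires a quantitative")
  expect_error(validate_channels(channel_spec(size = "ghost"), tab),
               "unknown factor")
  expect_error(size_scale(c("a", "b"), spec, kind = "qualitative"),
               "quantitative")
})

test_that("size maps linearly to area with clamping and monotonicity", {
  spec <- channel_spec(size = "v", size_range = c(10, 110),
                       size_domain = c(0, 100))
  a <- size_scale(c(0, 50, 100), spec)
  expect_equal(a, c(10, 60, 110))
  # clamped below/above
  expect_equal(size_scale(c(-5, 120), spec), c(10, 110))
  # monotone on random values
  set.seed(8)
  v <- runif(50, -10, 120)
  a <- size_scale(v, spec)
  expect_true(all(diff(a[order(v)]) >= 0))
  # missing -> NA (glyph omitted downstream)
  expect_true(is.na(size_scale(c(1, NA), spec)[2L]))
  # degenerate domain -> mid-range with warning
  expect_warning(mid <- size_scale(c(3, 3),
                                   channel_spec(size = "v",
                                                size_range = c(10, 110))),
                 "degenerate")
  expect_equal(mid, c(60, 60))
})

test_that("quantitative colors interpolate linearly in RGB between anchors", {
  spec <- channel_spec(color = "v", palette = c("#000000", "#FF0000"),
                       color_domain = c(0, 1))
  cols <- color_map(c(0, 0.5, 1), spec, "quantitative")
  expect_equal(cols[c(1L, 3L)], c("#000000", "#FF0000"))
  # midpoint is the channelwise anchor mean (255/2, up to hex rounding)
  expect_lte(abs(grDevices::col2rgb(cols[2L])[1L] - 127.5), 0.5)
  expect_equal(grDevices::col2rgb(cols[2L])[2L:3L], c(0, 0), ignore_attr = TRUE)
  # symmetric default palette centers zero on the middle anchor
  spec2 <- channel_spec(color = "v")
  cols2 <- color_map(c(-2, 0, 2), spec2, "quantitative")
  expect_equal(cols2[2L], "#FFFFFF")
  # missing -> neutral grey
  expect_equal(color_map(c(1, NA), spec, "quantitative")[2L], "grey80")
})

test_that("qualitative colors recycle the discrete palette in level order", {
  spec <- channel_spec(color = "v", palette = c("#111111", "#222222"))
  expect_warning(
    cols <- color_map(c("a", "b", "c"), spec, "qualitative",
                      levels = c("a", "b", "c")),
    "recycled")
  expect_equal(cols, c("#111111", "#222222", "#111111"))
})

test_that("text labels round half away from zero and pass labels verbatim", {
  spec <- channel_spec(text = "v")
  expect_equal(text_labels(c(66.6, 0.5, -0.5, 2.4), spec, "quantitative"),
               c("67", "1", "-1", "2"))
  expect_equal(text_labels(c("gain", NA), spec, "qualitative"), c("gain", ""))
  expect_equal(text_labels(c(1.234, NA), spec, "quantitative")[2L], "")
  fmt <- channel_spec(text = "v", text_format = "%.1f")
  expect_equal(text_labels(3.14, fmt, "quantitative"), "3.1")
})

test_that("qualitative shapes map injectively to symbols with a capacity cap", {
  spec <- channel_spec(shape = "v",
                       shape_symbols = c("circle", "square", "triangle",
                                         "diamond", "star"))
  s1 <- shape_encode(c("marker", "non-marker"), spec, "qualitative")
  expect_equal(s1, c("circle", "square"))
  # stable across calls
  expect_identical(shape_encode(c("marker", "non-marker"), spec, "qualitative"), s1)
  expect_error(
    shape_encode(letters[1:6], spec, "qualitative"),
    "capacity")
})

test_that("quantitative shapes become clamped fractions of the full disc", {
  spec <- channel_spec(shape = "v", shape_domain = c(0, 100))
  expect_equal(shape_encode(c(0, 50, 100), spec, "quantitative"),
               c(0, 0.5, 1))
  expect_equal(shape_encode(c(-10, 150), spec, "quantitative"), c(0, 1))
  set.seed(3)
  f <- shape_encode(runif(30, -50, 150), spec, "quantitative")
  expect_true(all(f >= 0 & f <= 1))
  # symbol_series quantizes into 5 bins
  spec2 <- channel_spec(shape = "v", shape_domain = c(0, 100),
                        shape_style = "symbol_series")
  f2 <- shape_encode(c(0, 10, 30, 60, 90, 100), spec2, "quantitative")
  expect_true(all(f2 %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_equal(f2[c(1L, 6L)], c(0, 1))
})

test_that("encoders are deterministic on identical input", {
  spec <- channel_spec(size = "a", color = "b", text = "c", shape = "d")
  set.seed(10)
  v <- runif(20, 0, 100)
  expect_identical(size_scale(v, spec), size_scale(v, spec))
  expect_identical(color_map(v, spec, "quantitative"),
                   color_map(v, spec, "quantitative"))
  expect_identical(shape_encode(v, spec, "quantitative"),
                   shape_encode(v, spec, "quantitative"))
})
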