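# Scene assembly: glyph grid + dendrograms + legends -> dot_scene.

#' Rendering options
#'
#' @param format output format, \code{"svg"} or \code{"png"}.
#' @param dpi raster resolution for PNG output (> 0).
#' @param font_family,font_size text style (points).
#' @param cell_size grid cell edge length in points (> 0).
#' @return a \code{render_options} list.
#' @export
render_options <- function(format = c("svg", "png"), dpi = 150,
                           font_family = "Helvetica", font_size = 11,
                           cell_size = 36) {
  format <- match.arg(format)
  if (dpi <= 0) stop("dpi must be > 0")
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(list(format = format, dpi = dpi, font_family = font_family,
                 font_size = font_size, cell_size = cell_size),
            class = "render_options")
}

# crude but deterministic text-extent estimate (points)
text_width <- function(labels, font_size) {
  if (!length(labels)) return(0)
  max(nchar(labels)) * font_size * 0.62
}

check_dend <- function(dend, levels, what) {
  if (is.null(dend)) return(levels)
  stopifnot(inherits(dend, "axis_dendrogram"))
  extra <- setdiff(dend$labels, levels)
  missing <- setdiff(levels, dend$labels)
  if (length(extra) || length(missing)) {
    stop(sprintf(
      "%s dendrogram labels do not match the axis levels (missing: %s; extra: %s)",
      what,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"))
  }
  dend$leaf_order
}

dendro_segments <- function(hc, leaf_coord) {
  # returns (along1, h1, along2, h2) per drawn segment, heights >= 0
  m <- hc$merge
  h <- hc$height
  node_pos <- numeric(nrow(m))
  node_h <- numeric(nrow(m))
  segs <- vector("list", nrow(m))
  pos_of <- function(id) {
    if (id < 0) leaf_coord[hc$labels[-id]] else node_pos[id]
  }
  h_of <- function(id) if (id < 0) 0 else node_h[id]
  for (k in seq_len(nrow(m))) {
    a <- m[k, 1L]; b <- m[k, 2L]
    xa <- pos_of(a); xb <- pos_of(b)
    segs[[k]] <- data.frame(
      a1 = c(xa, xb, xa), h1 = c(h_of(a), h_of(b), h[k]),
      a2 = c(xa, xb, xb), h2 = c(h[k], h[k], h[k]))
    node_pos[k] <- (xa + xb) / 2
    node_h[k] <- h[k]
  }
  do.call(rbind, segs)
}

#' Build legend block descriptions for the bound channels
#'
#' @param spec a validated [channel_spec()].
#' @param observed named list (per channel) with the observed \code{values},
#'   \code{kind} and qualitative \code{levels} of the bound factor, as
#'   assembled by [compose()].
#' @param show channels to keep (\code{TRUE} = all bound, \code{FALSE} =
#'   none, or a character subset); blocks are emitted in the fixed order
#'   size, color, shape, text.
#' @return list of legend block descriptions.
#' @export
build_legends <- function(spec, observed, show = TRUE) {
  if (isFALSE(show)) return(list())
  channels <- intersect(c("size", "color", "shape", "text"),
                        names(spec$assignments))
  if (is.character(show)) channels <- intersect(channels, show)
  blocks <- list()
  fmt <- function(v) formatC(signif(v, 3L), format = "fg", big.mark = "")
  for (ch in channels) {
    f <- spec$assignments[[ch]]
    obs <- observed[[ch]]
    blk <- switch(ch,
      size = {
        dom <- scale_domain(obs$values, spec$size_domain)
        vals <- c(dom[1L], mean(dom), dom[2L])
        data_frame <- data.frame(value = vals, label = fmt(vals),
                                 area = size_scale(vals, spec),
                                 stringsAsFactors = FALSE)
        list(channel = "size", title = f, type = "size_dots",
             entries = data_frame)
      },
      color = if (obs$kind == "quantitative") {
        has_neg <- any(obs$values < 0, na.rm = TRUE)
        dom <- spec$color_domain
        if (is.null(dom)) {
          dom <- if (has_neg) {
            m <- max(abs(obs$values), na.rm = TRUE); c(-m, m)
          } else scale_domain(obs$values, NULL)
        }
        ticks <- seq(dom[1L], dom[2L], length.out = 5L)
        list(channel = "color", title = f, type = "color_bar",
             domain = dom,
             ticks = data.frame(value = ticks, label = fmt(ticks),
                                stringsAsFactors = FALSE))
      } else {
        list(channel = "color", title = f, type = "color_swatches",
             entries = data.frame(
               level = obs$levels,
               color = color_map(obs$levels, spec, "qualitative", obs$levels),
               stringsAsFactors = FALSE))
      },
      shape = if (obs$kind == "qualitative") {
        list(channel = "shape", title = f, type = "shape_symbols",
             entries = data.frame(
               level = obs$levels,
               symbol = shape_encode(obs$levels, spec, "qualitative", obs$levels),
               stringsAsFactors = FALSE))
      } else {
        dom <- scale_domain(obs$values, spec$shape_domain)
        vals <- c(dom[1L], mean(dom), dom[2L])
        list(channel = "shape", title = f, type = "shape_fractions",
             entries = data.frame(fraction = c(0, 0.5, 1), value = vals,
                                  label = fmt(vals), stringsAsFactors = FALSE))
      },
      text = list(channel = "text", title = f, type = "text_note")
    )
    blocks[[length(blocks) + 1L]] <- blk
  }
  blocks
}

#' Compose a dot-plot scene
#'
#' Lays out one glyph per displayable (x, y) combination plus optional
#' dendrograms and per-channel legends into an absolute-coordinate scene
#' graph that [render()] serializes and [as_ggplot()] wraps.
#'
#' Axis orders follow the dendrogram leaf orders when dendrograms are given,
#' else the table's level order. When the size channel is bound,
#' combinations with a missing size value are omitted entirely; otherwise
#' every combination gets a glyph.
#'
#' @param table a [dot_table()].
#' @param spec a [channel_spec()]; validated against the table.
#' @param row_dend,col_dend optional [order_axis()] results for the y and x
#'   axis; their leaf sets must equal the axis level sets.
#' @param opts a [render_options()] list.
#' @param legends \code{TRUE} (all bound channels), \code{FALSE}, or a
#'   character subset of channels.
#' @param title optional plot title.
#' @return a \code{dot_scene}.
#' @export
compose <- function(table, spec, row_dend = NULL, col_dend = NULL,
                    opts = render_options(), legends = TRUE, title = NULL) {
  stopifnot(inherits(table, "dot_table"))
  validate_channels(spec, table)
  table <- complete_grid(table)
  kinds <- factor_kinds(table)

  xl <- check_dend(col_dend, x_levels(table), "column")
  yl <- check_dend(row_dend, y_levels(table), "row")

  nx <- length(xl); ny <- length(yl)
  cell <- opts$cell_size
  fs <- opts$font_size

  # observed values per bound channel, in canonical completed-grid order
  observed <- list()
  for (ch in names(spec$assignments)) {
    f <- spec$assignments[[ch]]
    vals <- table[[f]]
    observed[[ch]] <- list(
      values = vals, kind = kinds[[f]],
      levels = if (kinds[[f]] == "qualitative") unique(vals[!is.na(vals)]))
  }

  # glyph table ----------------------------------------------------------
  g <- data.frame(x_index = match(table[[1L]], xl),
                  y_index = match(table[[2L]], yl))
  size_bound <- "size" %in% names(spec$assignments)
  g$area <- if (size_bound) {
    size_scale(observed$size$values, spec)
  } else {
    rep(mean(spec$size_range), nrow(g))
  }
  g$fill <- if ("color" %in% names(spec$assignments)) {
    color_map(observed$color$values, spec, observed$color$kind,
              observed$color$levels)
  } else {
    rep("#3182BD", nrow(g))
  }
  if ("shape" %in% names(spec$assignments)) {
    enc <- shape_encode(observed$shape$values, spec, observed$shape$kind,
                        observed$shape$levels)
    if (observed$shape$kind == "qualitative") {
      g$symbol <- ifelse(is.na(enc), "circle", enc)
      g$fraction <- NA_real_
    } else {
      g$symbol <- ifelse(is.na(enc), "circle", "sector")
      g$fraction <- enc
    }
  } else {
    g$symbol <- "circle"
    g$fraction <- NA_real_
  }
  g$label <- if ("text" %in% names(spec$assignments)) {
    text_labels(observed$text$values, spec, observed$text$kind)
  } else {
    ""
  }
  if (size_bound) g <- g[!is.na(g$area), , drop = FALSE]
  g <- g[order(g$y_index, g$x_index), , drop = FALSE]  # row-major draw order
  rownames(g) <- NULL

  legend_blocks <- build_legends(spec, observed, legends)

  # layout ----------------------------------------------------------------
  margin <- 10
  grid_w <- nx * cell
  grid_h <- ny * cell
  row_band <- if (!is.null(row_dend) && nrow(row_dend$merges) > 0) 0.15 * grid_w else 0
  col_band <- if (!is.null(col_dend) && nrow(col_dend$merges) > 0) 0.15 * grid_h else 0
  ylab_w <- text_width(yl, fs) + 8
  xlab_h <- text_width(xl, fs) + 8
  title_h <- if (is.null(title)) 0 else fs * 1.6
  legend_w <- if (length(legend_blocks)) 118 else 0

  grid_x0 <- margin + row_band + ylab_w
  grid_y0 <- margin + title_h + col_band
  width <- grid_x0 + grid_w + 14 + legend_w + margin
  height <- grid_y0 + grid_h + xlab_h + margin

  b <- new_scene_builder()

  # dendrograms
  if (col_band > 0) {
    centers <- stats::setNames(grid_x0 + (seq_len(nx) - 0.5) * cell, xl)
    segs <- dendro_segments(col_dend$hclust, centers)
    maxh <- max(col_dend$heights)
    y_of <- function(h) grid_y0 - 4 - h / maxh * (col_band - 6)
    add_segment(b, segs$a1, y_of(segs$h1), segs$a2, y_of(segs$h2))
  }
  if (row_band > 0) {
    centers <- stats::setNames(grid_y0 + (seq_len(ny) - 0.5) * cell, yl)
    segs <- dendro_segments(row_dend$hclust, centers)
    maxh <- max(row_dend$heights)
    x_of <- function(h) margin + row_band - 4 - h / maxh * (row_band - 6)
    add_segment(b, x_of(segs$h1), segs$a1, x_of(segs$h2), segs$a2)
  }

  # glyphs (row-major)
  max_r <- sqrt(max(spec$size_range) / pi)
  for (i in seq_len(nrow(g))) {
    cx <- grid_x0 + (g$x_index[i] - 0.5) * cell
    cy <- grid_y0 + (g$y_index[i] - 0.5) * cell
    if (g$symbol[i] == "sector") {
      add_polygon(b, symbol_vertices("circle", cx, cy, g$area[i]),
                  fill = "none", stroke = "grey75", stroke_width = 0.8)
      if (!is.na(g$fraction[i]) && g$fraction[i] > 0) {
        add_polygon(b, sector_vertices(cx, cy, g$area[i], g$fraction[i]),
                    fill = g$fill[i], stroke = "grey35", stroke_width = 0.5)
      }
    } else {
      add_polygon(b, symbol_vertices(g$symbol[i], cx, cy, g$area[i]),
                  fill = g$fill[i], stroke = "grey35", stroke_width = 0.5)
    }
    if (nzchar(g$label[i])) {
      add_text(b, cx, cy + fs * 0.32, g$label[i], size = fs * 0.72,
               color = contrast_color(g$fill[i]))
    }
  }

  # axis labels
  add_text(b, rep(grid_x0 - 4, ny), grid_y0 + (seq_len(ny) - 0.5) * cell + fs * 0.32,
           yl, size = fs, anchor = "end")
  for (i in seq_len(nx)) {
    add_text(b, grid_x0 + (i - 0.5) * cell, grid_y0 + grid_h + 6,
             xl[i], size = fs, angle = 90, anchor = "start")
  }
  if (!is.null(title)) {
    add_text(b, width / 2, margin + fs, title, size = fs * 1.25)
  }

  # legends
  if (length(legend_blocks)) {
    lx <- grid_x0 + grid_w + 14
    draw_legends(b, legend_blocks, spec, lx, grid_y0, fs)
  }

  collect_scene(b, width, height, list(
    x_levels = xl, y_levels = yl, glyphs = g,
    legend_blocks = legend_blocks, options = opts, title = title,
    grid = list(x0 = grid_x0, y0 = grid_y0, cell = cell, nx = nx, ny = ny)))
}

draw_legends <- function(b, blocks, spec, lx, ly, fs) {
  y <- ly
  pad <- 6
  for (blk in blocks) {
    add_text(b, lx, y + fs, blk$title, size = fs, anchor = "start")
    y <- y + fs + pad
    if (blk$type == "size_dots") {
      for (i in seq_len(nrow(blk$entries))) {
        r <- sqrt(blk$entries$area[i] / pi)
        rowh <- max(2 * r + 4, fs + 4)
        cy <- y + rowh / 2
        add_polygon(b, symbol_vertices("circle", lx + 14, cy, blk$entries$area[i]),
                    fill = "grey65", stroke = "grey35", stroke_width = 0.5)
        add_text(b, lx + 32, cy + fs * 0.32, blk$entries$label[i],
                 size = fs * 0.9, anchor = "start")
        y <- y + rowh
      }
    } else if (blk$type == "color_bar") {
      bar_h <- 72; bar_w <- 12; steps <- 24L
      vals <- seq(blk$domain[2L], blk$domain[1L], length.out = steps)
      cols <- color_map(vals, spec, "quantitative")
      for (s in seq_len(steps)) {
        y0 <- y + (s - 1L) * bar_h / steps
        y1 <- y + s * bar_h / steps
        add_polygon(b, cbind(c(lx, lx + bar_w, lx + bar_w, lx),
                             c(y0, y0, y1, y1)),
                    fill = cols[s])
      }
      ticks <- blk$ticks
      for (i in seq_len(nrow(ticks))) {
        ty <- y + bar_h - (i - 1L) * bar_h / (nrow(ticks) - 1L)
        add_text(b, lx + bar_w + 5, ty + fs * 0.3, ticks$label[i],
                 size = fs * 0.85, anchor = "start")
      }
      y <- y + bar_h + 4
    } else if (blk$type == "color_swatches") {
      for (i in seq_len(nrow(blk$entries))) {
        add_polygon(b, cbind(c(lx, lx + 11, lx + 11, lx),
                             c(y, y, y + 11, y + 11)),
                    fill = blk$entries$color[i], stroke = "grey35",
                    stroke_width = 0.4)
        add_text(b, lx + 16, y + 5.5 + fs * 0.32, blk$entries$level[i],
                 size = fs * 0.9, anchor = "start")
        y <- y + 16
      }
    } else if (blk$type == "shape_symbols") {
      for (i in seq_len(nrow(blk$entries))) {
        add_polygon(b, symbol_vertices(blk$entries$symbol[i], lx + 7, y + 6, 70),
                    fill = "grey55", stroke = "grey35", stroke_width = 0.5)
        add_text(b, lx + 18, y + 6 + fs * 0.32, blk$entries$level[i],
                 size = fs * 0.9, anchor = "start")
        y <- y + 17
      }
    } else if (blk$type == "shape_fractions") {
      for (i in seq_len(nrow(blk$entries))) {
        area <- 110
        add_polygon(b, symbol_vertices("circle", lx + 8, y + 7, area),
                    fill = "none", stroke = "grey75", stroke_width = 0.8)
        if (blk$entries$fraction[i] > 0) {
          add_polygon(b, sector_vertices(lx + 8, y + 7, area,
                                         blk$entries$fraction[i]),
                      fill = "grey55", stroke = "grey35", stroke_width = 0.5)
        }
        add_text(b, lx + 21, y + 7 + fs * 0.32, blk$entries$label[i],
                 size = fs * 0.9, anchor = "start")
        y <- y + 19
      }
    } else if (blk$type == "text_note") {
      add_text(b, lx, y + fs * 0.9, "(dot text)", size = fs * 0.85,
               anchor = "start")
      y <- y + fs + 2
    }
    y <- y + 14
  }
  invisible(b)
}

#' Split interaction columns into partner sub-columns
#'
#' For cell-communication layouts where each x level names an interacting
#' pair (e.g. \code{"TAM|TP1"}), each column is split into two adjacent
#' sub-columns carrying the two partners' own values of one unified
#' quantitative display factor (e.g. each partner gene's expression in its
#' own population).
#'
#' @param table a [dot_table()] whose x levels each contain
#'   \code{pair_separator} exactly once.
#' @param left_factor,right_factor quantitative display factors supplying
#'   the left and right sub-column values.
#' @param pair_separator separator string (fixed, not regex).
#' @param value_name name of the unified factor in the result (default
#'   \code{"<left>_<right>"}).
#' @param carry which side keeps the remaining display factors:
#'   \code{"both"} (duplicated), \code{"left"} or \code{"right"} (missing on
#'   the other side).
#' @return a [dot_table()] with twice the x levels and twice the rows.
#' @export
split_columns <- function(table, left_factor, right_factor,
                          pair_separator = "|", value_name = NULL,
                          carry = c("both", "left", "right")) {
  stopifnot(inherits(table, "dot_table"))
  carry <- match.arg(carry)
  kinds <- factor_kinds(table)
  for (f in c(left_factor, right_factor)) {
    if (!f %in% names(kinds)) stop("unknown factor: ", f)
    if (kinds[[f]] != "quantitative") {
      stop(sprintf("split factors must be quantitative; '%s' is qualitative", f))
    }
  }
  xl <- x_levels(table)
  n_sep <- lengths(regmatches(xl, gregexpr(pair_separator, xl, fixed = TRUE)))
  bad <- xl[n_sep != 1L]
  if (length(bad)) {
    stop(sprintf(
      "x level(s) must contain the separator '%s' exactly once: %s",
      pair_separator, paste(bad, collapse = ", ")))
  }
  if (is.null(value_name)) value_name <- paste(left_factor, right_factor, sep = "_")

  parts <- strsplit(xl, pair_separator, fixed = TRUE)
  left_lab <- stats::setNames(
    paste0(xl, ":", vapply(parts, `[`, "", 1L)), xl)
  right_lab <- stats::setNames(
    paste0(xl, ":", vapply(parts, `[`, "", 2L)), xl)
  new_xl <- as.vector(rbind(left_lab[xl], right_lab[xl]))

  others <- setdiff(names(kinds), c(left_factor, right_factor))
  make_side <- function(side_lab, value_col, keep_others) {
    df <- data.frame(x = side_lab[table[[1L]]], y = table[[2L]],
                     stringsAsFactors = FALSE)
    names(df) <- names(table)[1:2]
    df[[value_name]] <- table[[value_col]]
    for (f in others) {
      df[[f]] <- if (keep_others) {
        table[[f]]
      } else if (is.numeric(table[[f]])) {
        rep(NA_real_, nrow(table))
      } else {
        rep(NA_character_, nrow(table))
      }
    }
    df
  }
  out <- rbind(
    make_side(left_lab, left_factor, carry %in% c("both", "left")),
    make_side(right_lab, right_factor, carry %in% c("both", "right"))
  )
  dot_table(out,
            factor_kinds = c(stats::setNames("quantitative", value_name),
                             kinds[others]),
            x_levels = new_xl, y_levels = y_levels(table))
}
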