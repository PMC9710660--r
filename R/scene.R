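# Scene primitives: every drawable element is reduced to polygons, line
# segments and text anchors in one absolute coordinate system (points,
# origin top-left, y increasing downward). The SVG serializer and the
# ggplot2 handle both draw exactly these primitives.

CIRCLE_SEGMENTS <- 48L

# Unit outlines (enclosing circle radius 1) with their enclosed area, used
# to scale every symbol so that its polygon AREA equals the requested area.
unit_symbol <- function(symbol) {
  t <- switch(symbol,
    circle = {
      a <- seq(0, 2 * pi, length.out = CIRCLE_SEGMENTS + 1L)[-(CIRCLE_SEGMENTS + 1L)]
      cbind(cos(a), sin(a))
    },
    square = cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)) / sqrt(2),
    triangle = {
      a <- -pi / 2 + 2 * pi * (0:2) / 3
      cbind(cos(a), sin(a))
    },
    diamond = cbind(c(0, 1, 0, -1), c(-1, 0, 1, 0)),
    star = {
      a <- -pi / 2 + pi * (0:9) / 5
      r <- rep(c(1, 0.45), 5L)
      cbind(r * cos(a), r * sin(a))
    },
    cross = {
      w <- 0.34
      cbind(c(-w, w, w, 1, 1, w, w, -w, -w, -1, -1, -w),
            c(-1, -1, -w, -w, w, w, 1, 1, w, w, -w, -w))
    },
    hexagon = {
      a <- pi / 6 + 2 * pi * (0:5) / 6
      cbind(cos(a), sin(a))
    },
    stop("unknown symbol: ", symbol)
  )
  t
}

polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Vertices of `symbol` centered at (cx, cy) with polygon area `area`.
symbol_vertices <- function(symbol, cx, cy, area) {
  u <- unit_symbol(symbol)
  s <- sqrt(area / polygon_area(u))
  cbind(cx + s * u[, 1L], cy + s * u[, 2L])
}

# Filled circular sector of angle 2*pi*fraction starting at 12 o'clock,
# clockwise, for a disc of area `area` (radius from the FULL disc so the
# sector is readable as a filled fraction of the outline circle).
sector_vertices <- function(cx, cy, area, fraction) {
  r <- sqrt(area / pi)
  if (fraction >= 1) {
    return(symbol_vertices("circle", cx, cy, area))
  }
  n <- max(2L, ceiling(CIRCLE_SEGMENTS * fraction))
  a <- -pi / 2 + seq(0, 2 * pi * fraction, length.out = n + 1L)
  cbind(c(cx, cx + r * cos(a)), c(cy, cy + r * sin(a)))
}

# Mutable-by-copy scene builder -----------------------------------------

new_scene_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$polygons <- list()
  env$poly_styles <- list()
  env$segments <- list()
  env$texts <- list()
  env$next_id <- 1L
  env
}

add_polygon <- function(b, xy, fill, stroke = "none", stroke_width = 0) {
  id <- b$next_id
  b$next_id <- id + 1L
  b$polygons[[id]] <- data.frame(id = id, x = xy[, 1L], y = xy[, 2L])
  b$poly_styles[[id]] <- data.frame(id = id, fill = fill, stroke = stroke,
                                    stroke_width = stroke_width,
                                    stringsAsFactors = FALSE)
  invisible(id)
}

add_segment <- function(b, x1, y1, x2, y2, color = "grey30", width = 1) {
  b$segments[[length(b$segments) + 1L]] <-
    data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, color = color,
               width = width, stringsAsFactors = FALSE)
  invisible(b)
}

add_text <- function(b, x, y, label, size, angle = 0, anchor = "middle",
                     color = "#000000") {
  keep <- nzchar(label)
  if (!any(keep)) return(invisible(b))
  b$texts[[length(b$texts) + 1L]] <-
    data.frame(x = x[keep], y = y[keep], label = label[keep], size = size,
               angle = angle, anchor = anchor, color = color,
               stringsAsFactors = FALSE)
  invisible(b)
}

collect_scene <- function(b, width, height, meta) {
  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  scene <- c(list(
    width = width, height = height,
    polygons = bind(b$polygons, data.frame(id = integer(), x = numeric(),
                                           y = numeric())),
    poly_styles = bind(b$poly_styles,
                       data.frame(id = integer(), fill = character(),
                                  stroke = character(),
                                  stroke_width = numeric())),
    segments = bind(b$segments,
                    data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                               y2 = numeric(), color = character(),
                               width = numeric())),
    texts = bind(b$texts,
                 data.frame(x = numeric(), y = numeric(), label = character(),
                            size = numeric(), angle = numeric(),
                            anchor = character(), color = character()))
  ), meta)
  structure(scene, class = "dot_scene")
}

#' @export
print.dot_scene <- function(x, ...) {
  cat(sprintf("<dot_scene> %.0f x %.0f pt; %d glyphs (%d x-levels x %d y-levels)\n",
              x$width, x$height, nrow(x$glyphs),
              length(x$x_levels), length(x$y_levels)))
  invisible(x)
}

# Perceived luminance -> black or white overlay text.
contrast_color <- function(fill) {
  rgb <- grDevices::col2rgb(fill)
  lum <- 0.299 * rgb[1L, ] + 0.587 * rgb[2L, ] + 0.114 * rgb[3L, ]
  ifelse(lum > 140, "#000000", "#FFFFFF")
}
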