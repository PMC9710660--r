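# Serialization of a dot_scene: deterministic SVG 1.1 by direct element
# writing (fixed element order: background, dendrogram segments, glyph and
# legend polygons, texts; fixed 2-decimal coordinate formatting; no
# timestamps or generated ids), and a ggplot2 handle drawing the same
# primitives for interactive customization / PNG rasterization.

utils::globalVariables(c("x", "y", "id", "fill", "stroke"))

num <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_color <- function(x) {
  out <- rep("none", length(x))
  ok <- x != "none"
  if (any(ok)) {
    out[ok] <- toupper(grDevices::rgb(t(grDevices::col2rgb(x[ok])),
                                      maxColorValue = 255))
  }
  out
}

#' Serialize a scene to SVG text
#'
#' The output is byte-deterministic for identical scene + options: elements
#' are written in a fixed order with fixed numeric formatting and contain no
#' timestamps or random identifiers.
#'
#' @param scene a \code{dot_scene} from [compose()].
#' @return a character vector of SVG lines.
#' @export
svg_lines <- function(scene) {
  stopifnot(inherits(scene, "dot_scene"))
  opts <- scene$options
  out <- character(0)
  out <- c(out, sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%spt" height="%spt" viewBox="0 0 %s %s">',
    num(scene$width), num(scene$height), num(scene$width), num(scene$height)))
  out <- c(out, sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
                        num(scene$width), num(scene$height)))
  s <- scene$segments
  if (nrow(s)) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      num(s$x1), num(s$y1), num(s$x2), num(s$y2), svg_color(s$color),
      num(s$width)))
  }
  p <- scene$polygons
  st <- scene$poly_styles
  if (nrow(st)) {
    pts <- vapply(split(p, p$id), function(d) {
      paste(paste0(num(d$x), ",", num(d$y)), collapse = " ")
    }, "")
    pts <- pts[as.character(st$id)]
    stroke <- ifelse(st$stroke == "none", "none", svg_color(st$stroke))
    out <- c(out, sprintf(
      '<polygon points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      pts, svg_color(st$fill), stroke, num(st$stroke_width)))
  }
  tx <- scene$texts
  if (nrow(tx)) {
    anchor <- c(start = "start", middle = "middle", end = "end")[tx$anchor]
    rot <- ifelse(tx$angle != 0,
                  sprintf(' transform="rotate(%s %s %s)"',
                          num(tx$angle), num(tx$x), num(tx$y)),
                  "")
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%s" text-anchor="%s" fill="%s"%s>%s</text>',
      num(tx$x), num(tx$y), opts$font_family, num(tx$size), anchor,
      svg_color(tx$color), rot, xml_escape(tx$label)))
  }
  c(out, "</svg>")
}

#' Render a scene to a file
#'
#' SVG output is written directly (byte-deterministic, see [svg_lines()]);
#' PNG output rasterizes the [as_ggplot()] handle at \code{opts$dpi}.
#'
#' @param scene a \code{dot_scene}.
#' @param path output path; the format is taken from the extension
#'   (\code{.svg} or \code{.png}).
#' @param opts [render_options()]; defaults to the options the scene was
#'   composed with.
#' @return the path, invisibly.
#' @export
render <- function(scene, path, opts = NULL) {
  stopifnot(inherits(scene, "dot_scene"))
  if (is.null(opts)) opts <- scene$options
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) {
    stop("unsupported output format '", ext, "'; use .svg or .png")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (ext == "svg") {
    con <- file(path, open = "wb")  # byte-exact: no platform newline mangling
    on.exit(close(con))
    writeLines(svg_lines(scene), con, sep = "\n", useBytes = TRUE)
  } else {
    gg <- as_ggplot(scene)
    ggplot2::ggsave(path, gg, width = scene$width / 72,
                    height = scene$height / 72, units = "in", dpi = opts$dpi)
  }
  invisible(path)
}

#' Convert a scene to an extensible ggplot2 object
#'
#' Draws the scene primitives (polygons, dendrogram segments, texts) with
#' fixed coordinates, so the handle renders the same picture as [render()];
#' callers can add further ggplot2 layers before saving. Each call returns
#' an independent object.
#'
#' @param scene a \code{dot_scene}.
#' @return a ggplot object.
#' @export
as_ggplot <- function(scene) {
  stopifnot(inherits(scene, "dot_scene"))
  opts <- scene$options
  gg <- ggplot2::ggplot() +
    ggplot2::theme_void() +
    ggplot2::coord_fixed(xlim = c(0, scene$width), ylim = c(scene$height, 0),
                         expand = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_colour_identity() +
    ggplot2::theme(plot.background =
                     ggplot2::element_rect(fill = "#FFFFFF", color = NA))
  s <- scene$segments
  if (nrow(s)) {
    gg <- gg + ggplot2::annotate("segment", x = s$x1, y = s$y1,
                                 xend = s$x2, yend = s$y2,
                                 colour = s$color, linewidth = s$width / 2)
  }
  p <- scene$polygons
  st <- scene$poly_styles
  if (nrow(st)) {
    pd <- merge(p, st, by = "id", sort = FALSE)
    pd <- pd[order(pd$id), ]
    pd$fill <- ifelse(pd$fill == "none", NA, pd$fill)
    pd$stroke <- ifelse(pd$stroke == "none", NA, pd$stroke)
    gg <- gg + ggplot2::geom_polygon(
      data = pd,
      ggplot2::aes(x = x, y = y, group = id, fill = fill, colour = stroke),
      linewidth = 0.3)
  }
  tx <- scene$texts
  if (nrow(tx)) {
    hjust <- c(start = 0, middle = 0.5, end = 1)[tx$anchor]
    gg <- gg + ggplot2::annotate(
      "text", x = tx$x, y = tx$y, label = tx$label,
      size = tx$size / ggplot2::.pt, angle = -tx$angle, hjust = hjust,
      colour = tx$color, family = "sans")
  }
  gg
}
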