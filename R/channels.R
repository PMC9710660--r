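# Channel specification and the four value -> visual-channel encoders.
# Compatibility rule: size accepts quantitative factors only; color, text
# and shape accept either kind with an adapted rendering.

CHANNELS <- c("size", "color", "text", "shape")
DEFAULT_SYMBOLS <- c("circle", "square", "triangle", "diamond", "star",
                     "cross", "hexagon")
# Okabe-Ito without black: colorblind-safe discrete default.
DEFAULT_DISCRETE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
                      "#0072B2", "#D55E00", "#CC79A7")

#' Specify how display factors map onto dot channels
#'
#' Assigns factors (by column name) to the four channels. Each channel takes
#' at most one factor, and at least one channel must be bound; a factor may
#' drive several channels (e.g. a percentage shown as both dot size and dot
#' text). The size channel accepts only quantitative factors (checked
#' against a table by [validate_channels()]).
#'
#' @param size,color,text,shape factor names (or NULL to leave unbound).
#' @param size_range dot area range (min, max) in squared display units
#'   (pt^2); areas scale linearly with the value.
#' @param size_domain optional (lo, hi) value bounds for the size scale;
#'   values outside are clamped. Default: observed range.
#' @param color_domain optional (lo, hi) bounds for a quantitative color
#'   scale.
#' @param palette for a quantitative color factor: character vector of >= 2
#'   anchor colors interpolated linearly in RGB (default blue-white-red
#'   symmetric around 0 when negatives are present, else white-blue); for a
#'   qualitative factor: discrete color list cycled over levels.
#' @param na_color color for missing values.
#' @param shape_symbols ordered symbol names for a qualitative shape factor
#'   (levels beyond the list are a capacity error).
#' @param shape_style quantitative shape rendering: \code{"fraction_pie"}
#'   (filled circular sector over a light full-circle outline, angle
#'   proportional to the value) or \code{"symbol_series"} (value binned into
#'   at most 5 equal-width bins rendered as sectors at the bin fractions).
#' @param shape_domain optional (lo, hi) bounds for the quantitative shape
#'   fraction.
#' @param text_format \code{NULL} for the default (round half away from
#'   zero to integer), an \code{sprintf} format string, or a function.
#' @return an object of class \code{channel_spec}.
#' @export
channel_spec <- function(size = NULL, color = NULL, text = NULL, shape = NULL,
                         size_range = c(4, 420), size_domain = NULL,
                         color_domain = NULL, palette = NULL,
                         na_color = "grey80",
                         shape_symbols = DEFAULT_SYMBOLS,
                         shape_style = c("fraction_pie", "symbol_series"),
                         shape_domain = NULL, text_format = NULL) {
  assignments <- list(size = size, color = color, text = text, shape = shape)
  assignments <- assignments[!vapply(assignments, is.null, TRUE)]
  if (!length(assignments)) {
    stop("at least one channel must be bound to a factor")
  }
  if (!all(vapply(assignments, function(a) is.character(a) && length(a) == 1L, TRUE))) {
    stop("each channel takes a single factor name")
  }
  if (length(size_range) != 2L || size_range[1L] < 0 ||
      size_range[2L] <= size_range[1L]) {
    stop("size_range must be (min >= 0, max > min)")
  }
  structure(list(assignments = assignments,
                 size_range = as.numeric(size_range),
                 size_domain = size_domain,
                 color_domain = color_domain,
                 palette = palette,
                 na_color = na_color,
                 shape_symbols = shape_symbols,
                 shape_style = match.arg(shape_style),
                 shape_domain = shape_domain,
                 text_format = text_format),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec>\n")
  for (ch in names(x$assignments)) {
    cat(sprintf("  %-5s <- %s\n", ch, x$assignments[[ch]]))
  }
  invisible(x)
}

#' Validate a channel spec against a dot table
#'
#' Checks that every bound factor exists in the table and that the size
#' channel is bound to a quantitative factor.
#'
#' @param spec a [channel_spec()].
#' @param table a [dot_table()].
#' @return the spec, invisibly; errors otherwise.
#' @export
validate_channels <- function(spec, table) {
  stopifnot(inherits(spec, "channel_spec"))
  kinds <- factor_kinds(table)
  for (ch in names(spec$assignments)) {
    f <- spec$assignments[[ch]]
    if (!f %in% names(kinds)) {
      stop(sprintf("channel '%s' is bound to unknown factor '%s'", ch, f))
    }
    if (ch == "size" && kinds[[f]] != "quantitative") {
      stop(sprintf(
        "the size channel requires a quantitative factor, but '%s' is qualitative", f))
    }
  }
  invisible(spec)
}

scale_domain <- function(values, domain) {
  if (!is.null(domain)) {
    stopifnot(length(domain) == 2L)
    return(as.numeric(domain))
  }
  r <- range(values, na.rm = TRUE)
  if (!all(is.finite(r))) c(0, 1) else r
}

#' Map quantitative values to dot areas
#'
#' Linear map of value to area (not radius): \code{area = min_area +
#' (v - lo)/(hi - lo) * (max_area - min_area)}, clamped to the range.
#' Missing values give \code{NA} (the glyph is omitted downstream).
#'
#' @param values numeric vector.
#' @param spec a [channel_spec()].
#' @param kind factor kind; qualitative is a type error.
#' @return numeric vector of areas.
#' @export
size_scale <- function(values, spec, kind = "quantitative") {
  if (kind != "quantitative") {
    stop("the size channel requires a quantitative factor")
  }
  values <- as.numeric(values)
  dom <- scale_domain(values, spec$size_domain)
  lo <- dom[1L]; hi <- dom[2L]
  rng <- spec$size_range
  if (hi == lo) {
    warning("degenerate size domain (hi == lo); using mid-range area")
    out <- rep(mean(rng), length(values))
    out[is.na(values)] <- NA_real_
    return(out)
  }
  f <- pmin(1, pmax(0, (values - lo) / (hi - lo)))
  rng[1L] + f * (rng[2L] - rng[1L])
}

#' Map values to colors
#'
#' Quantitative values are interpolated piecewise-linearly in RGB between
#' the palette anchors over the color domain (symmetric around 0 by default
#' when negatives are present). Qualitative levels are assigned colors
#' cyclically from the discrete palette in level order (with a warning when
#' levels outnumber colors). Missing values map to \code{na_color}.
#'
#' @param values numeric or character vector.
#' @param spec a [channel_spec()].
#' @param kind \code{"quantitative"} or \code{"qualitative"}.
#' @param levels level order for qualitative values (default first
#'   appearance).
#' @return character vector of hex colors.
#' @export
color_map <- function(values, spec, kind = NULL, levels = NULL) {
  if (is.null(kind)) {
    kind <- if (is.numeric(values)) "quantitative" else "qualitative"
  }
  if (kind == "quantitative") {
    values <- as.numeric(values)
    anchors <- spec$palette
    has_neg <- any(values < 0, na.rm = TRUE)
    if (is.null(anchors)) {
      anchors <- if (has_neg) c("#2166AC", "#FFFFFF", "#B2182B")
                 else c("#FFFFFF", "#2166AC")
    }
    dom <- spec$color_domain
    if (is.null(dom)) {
      if (has_neg) {
        m <- max(abs(values), na.rm = TRUE)
        dom <- c(-m, m)
      } else {
        dom <- scale_domain(values, NULL)
      }
    }
    out <- rep(spec$na_color, length(values))
    ok <- !is.na(values)
    if (any(ok)) {
      if (dom[2L] == dom[1L]) {
        f <- rep(0.5, sum(ok))
      } else {
        f <- pmin(1, pmax(0, (values[ok] - dom[1L]) / (dom[2L] - dom[1L])))
      }
      ramp <- grDevices::colorRamp(anchors, space = "rgb", interpolate = "linear")
      rgb <- ramp(f)
      out[ok] <- grDevices::rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L], maxColorValue = 255)
    }
    out
  } else {
    values <- as.character(values)
    if (is.null(levels)) levels <- unique(values[!is.na(values)])
    pal <- spec$palette
    if (is.null(pal)) pal <- DEFAULT_DISCRETE
    if (length(levels) > length(pal)) {
      warning(sprintf("%d levels but %d colors; colors are recycled",
                      length(levels), length(pal)))
    }
    cols <- pal[((seq_along(levels) - 1L) %% length(pal)) + 1L]
    out <- cols[match(values, levels)]
    out[is.na(out)] <- spec$na_color
    out
  }
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Format values as dot text labels
#'
#' Quantitative values use \code{text_format} (default: round half away
#' from zero to integer); qualitative values pass through verbatim; missing
#' values become the empty string.
#'
#' @inheritParams color_map
#' @return character vector.
#' @export
text_labels <- function(values, spec, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (is.numeric(values)) "quantitative" else "qualitative"
  }
  out <- character(length(values))
  ok <- !is.na(values)
  if (kind == "quantitative") {
    v <- as.numeric(values)[ok]
    fmt <- spec$text_format
    out[ok] <- if (is.null(fmt)) {
      sprintf("%d", as.integer(round_half_away(v)))
    } else if (is.function(fmt)) {
      as.character(fmt(v))
    } else {
      sprintf(fmt, v)
    }
  } else {
    out[ok] <- as.character(values)[ok]
  }
  out
}

#' Encode values as dot shapes
#'
#' Qualitative levels map injectively onto the symbol list in level order
#' (capacity error when levels outnumber symbols). Quantitative values with
#' \code{shape_style = "fraction_pie"} become fractions in [0, 1]
#' (value rescaled over the shape domain, clamped), rendered downstream as a
#' filled circular sector of angle 2*pi*fraction; with
#' \code{"symbol_series"} the fraction is quantized to at most 5 equal-width
#' bins.
#'
#' @inheritParams color_map
#' @return for qualitative input, a character vector of symbol names; for
#'   quantitative input, a numeric vector of fractions in [0, 1] (NA for
#'   missing).
#' @export
shape_encode <- function(values, spec, kind = NULL, levels = NULL) {
  if (is.null(kind)) {
    kind <- if (is.numeric(values)) "quantitative" else "qualitative"
  }
  if (kind == "qualitative") {
    values <- as.character(values)
    if (is.null(levels)) levels <- unique(values[!is.na(values)])
    if (length(levels) > length(spec$shape_symbols)) {
      stop(sprintf("shape channel capacity exceeded: %d levels but %d symbols",
                   length(levels), length(spec$shape_symbols)))
    }
    spec$shape_symbols[match(values, levels)]
  } else {
    values <- as.numeric(values)
    dom <- scale_domain(values, spec$shape_domain)
    if (dom[2L] == dom[1L]) {
      f <- ifelse(is.na(values), NA_real_, 0.5)
    } else {
      f <- pmin(1, pmax(0, (values - dom[1L]) / (dom[2L] - dom[1L])))
    }
    if (spec$shape_style == "symbol_series") {
      nb <- 5L
      f <- ifelse(is.na(f), NA_real_, round_half_away(f * (nb - 1L)) / (nb - 1L))
    }
    f
  }
}
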