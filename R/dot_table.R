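# Tokens treated as missing on read; written back as "NA".
MISSING_TOKENS <- c("", "na", "nan")

#' Infer whether a raw column is quantitative or qualitative
#'
#' A column is quantitative when every non-missing value parses as a finite
#' real number; otherwise it is qualitative. Missing tokens (empty string,
#' \code{"NA"}, \code{"NaN"}, case-insensitive) are ignored during inference.
#'
#' @param values character vector of raw values.
#' @return \code{"quantitative"} or \code{"qualitative"}.
#' @examples
#' infer_factor_kind(c("1.5", "2", "-3"))       # quantitative
#' infer_factor_kind(c("gain", "loss"))         # qualitative
#' infer_factor_kind(c("1", "NA", "2"))         # quantitative
#' @export
infer_factor_kind <- function(values) {
  if (length(values) == 0L) {
    stop("cannot infer factor kind from an empty column")
  }
  raw <- as.character(values)
  keep <- !is_missing_token(raw)
  if (!any(keep)) {
    stop("cannot infer factor kind: all values missing; declare the kind explicitly")
  }
  num <- suppressWarnings(as.numeric(raw[keep]))
  if (all(!is.na(num) & is.finite(num))) "quantitative" else "qualitative"
}

is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% MISSING_TOKENS
}

#' Construct a validated dot-plot table
#'
#' A dot table is a long-format data frame whose first column holds the
#' x-axis factor levels, second column the y-axis factor levels, and whose
#' remaining 1--4 columns are display factors (each quantitative or
#' qualitative). Each (x, y) pair may occur at most once. Axis level order
#' is first appearance unless overridden.
#'
#' @param data a data.frame with at least three columns and one row.
#' @param factor_kinds optional named character vector mapping display-factor
#'   names to \code{"quantitative"}/\code{"qualitative"}; unnamed factors are
#'   inferred with [infer_factor_kind()].
#' @param x_levels,y_levels optional explicit level orders (must be a
#'   permutation of the observed levels).
#' @return an object of class \code{dot_table}: the data.frame with
#'   attributes \code{x_levels}, \code{y_levels} and \code{factor_kinds}.
#' @export
dot_table <- function(data, factor_kinds = NULL, x_levels = NULL, y_levels = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (ncol(data) < 3L) {
    stop("a dot table needs at least 3 columns (x, y, one display factor); got ",
         ncol(data))
  }
  if (nrow(data) < 1L) {
    stop("a dot table needs at least one data row")
  }
  n_factors <- ncol(data) - 2L
  if (n_factors > 4L) {
    stop("at most 4 display factors are supported (one per channel); got ",
         n_factors)
  }

  xs <- as.character(data[[1L]])
  ys <- as.character(data[[2L]])
  if (anyNA(xs) || anyNA(ys) || any(is_missing_token(xs)) || any(is_missing_token(ys))) {
    stop("axis columns may not contain missing values")
  }
  key <- paste(xs, ys, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    pair <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicated (x, y) combination: (%s, %s)", pair[1L], pair[2L]))
  }

  obs_x <- unique(xs)
  obs_y <- unique(ys)
  x_levels <- check_levels(x_levels, obs_x, "x")
  y_levels <- check_levels(y_levels, obs_y, "y")

  fac_names <- names(data)[-(1:2)]
  kinds <- character(n_factors)
  names(kinds) <- fac_names
  for (nm in fac_names) {
    raw <- data[[nm]]
    if (!is.null(factor_kinds) && nm %in% names(factor_kinds)) {
      k <- match.arg(factor_kinds[[nm]], c("quantitative", "qualitative"))
    } else if (is.numeric(raw)) {
      k <- "quantitative"
    } else if (all(is_missing_token(as.character(raw)))) {
      stop(sprintf("factor '%s' is entirely missing; declare its kind explicitly", nm))
    } else {
      k <- infer_factor_kind(as.character(raw))
    }
    kinds[[nm]] <- k
    data[[nm]] <- coerce_factor_column(raw, k, nm)
  }
  bad <- setdiff(names(factor_kinds), fac_names)
  if (length(bad)) {
    stop("declared kinds for unknown factors: ", paste(bad, collapse = ", "))
  }

  data[[1L]] <- xs
  data[[2L]] <- ys
  structure(data,
            x_levels = x_levels, y_levels = y_levels, factor_kinds = kinds,
            class = c("dot_table", "data.frame"))
}

check_levels <- function(levels, observed, axis) {
  if (is.null(levels)) return(observed)
  levels <- as.character(levels)
  if (!setequal(levels, observed) || length(levels) != length(observed)) {
    stop(sprintf("%s_levels must be a permutation of the observed %s levels", axis, axis))
  }
  levels
}

coerce_factor_column <- function(raw, kind, name) {
  chr <- as.character(raw)
  chr[is_missing_token(chr)] <- NA_character_
  if (kind == "quantitative") {
    num <- suppressWarnings(as.numeric(chr))
    bad <- !is.na(chr) & (is.na(num) | !is.finite(num))
    if (any(bad)) {
      stop(sprintf("factor '%s' is declared quantitative but contains non-numeric value '%s'",
                   name, chr[bad][1L]))
    }
    num
  } else {
    chr
  }
}

#' @export
print.dot_table <- function(x, ...) {
  kinds <- factor_kinds(x)
  cat(sprintf("<dot_table> %d rows; %d x-levels x %d y-levels; %d display factor(s)\n",
              nrow(x), length(x_levels(x)), length(y_levels(x)), length(kinds)))
  cat(paste(sprintf("  %s [%s]", names(kinds), kinds), collapse = "\n"), "\n")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Accessors for dot-table metadata
#'
#' @param table a [dot_table()].
#' @return \code{x_levels}/\code{y_levels}: character vectors of axis levels
#'   in display order; \code{factor_kinds}: named character vector of
#'   \code{"quantitative"}/\code{"qualitative"}; \code{factor_names}: the
#'   display-factor column names.
#' @export
x_levels <- function(table) attr(table, "x_levels")

#' @rdname x_levels
#' @export
y_levels <- function(table) attr(table, "y_levels")

#' @rdname x_levels
#' @export
factor_kinds <- function(table) attr(table, "factor_kinds")

#' @rdname x_levels
#' @export
factor_names <- function(table) names(factor_kinds(table))

#' Read a dot table from a delimited file
#'
#' Reads CSV or TSV (header required, UTF-8). The delimiter is sniffed from
#' the header line unless given. Empty strings, \code{"NA"} and \code{"NaN"}
#' (case-insensitive) are read as missing.
#'
#' @param path file path.
#' @param sep field separator; \code{NULL} to sniff ("," vs tab).
#' @inheritParams dot_table
#' @return a [dot_table()].
#' @export
read_dot_table <- function(path, sep = NULL, factor_kinds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           comment.char = "")
  if (ncol(raw) < 3L) {
    stop(sprintf("input file '%s' has %d column(s); a dot table needs at least 3 (x, y, factor)",
                 path, ncol(raw)))
  }
  if (nrow(raw) < 1L) stop(sprintf("input file '%s' has no data rows", path))
  dot_table(raw, factor_kinds = factor_kinds)
}

#' Write a dot table to a delimited file
#'
#' Missing values are written as \code{"NA"}; the result re-parses to an
#' identical table with [read_dot_table()].
#'
#' @param table a [dot_table()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_dot_table <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep, quote = TRUE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Complete a dot table to a full (x, y) grid
#'
#' Every combination of x and y levels appears exactly once in the result;
#' combinations absent from the input carry missing values for all display
#' factors. Supplied values are never altered. Rows are ordered x-major
#' (all y levels of the first x level, then the next), which makes the
#' operation idempotent.
#'
#' @param table a [dot_table()].
#' @return a completed [dot_table()].
#' @export
complete_grid <- function(table) {
  xl <- x_levels(table); yl <- y_levels(table)
  full <- data.frame(
    x = rep(xl, each = length(yl)),
    y = rep(yl, times = length(xl)),
    stringsAsFactors = FALSE
  )
  names(full) <- names(table)[1:2]
  key_full <- paste(full[[1L]], full[[2L]], sep = "\r")
  key_have <- paste(table[[1L]], table[[2L]], sep = "\r")
  idx <- match(key_full, key_have)
  for (nm in factor_names(table)) {
    full[[nm]] <- table[[nm]][idx]
  }
  dot_table(full, factor_kinds = factor_kinds(table),
            x_levels = xl, y_levels = yl)
}

#' Pivot one display factor to a wide matrix
#'
#' @param table a completed [dot_table()] (see [complete_grid()]).
#' @param factor display-factor name.
#' @param axis which axis supplies the matrix rows: \code{"x"} gives a
#'   matrix with one row per x level and one column per y level; \code{"y"}
#'   gives the transpose.
#' @return a numeric or character matrix with level dimnames; missing stays
#'   \code{NA}.
#' @export
pivot_wide <- function(table, factor, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!factor %in% factor_names(table)) {
    stop(sprintf("unknown factor '%s'; available: %s", factor,
                 paste(factor_names(table), collapse = ", ")))
  }
  table <- complete_grid(table)
  xl <- x_levels(table); yl <- y_levels(table)
  vals <- table[[factor]]
  i <- match(table[[1L]], xl)
  j <- match(table[[2L]], yl)
  fill <- if (is.numeric(vals)) NA_real_ else NA_character_
  m <- matrix(fill, nrow = length(xl), ncol = length(yl),
              dimnames = list(xl, yl))
  m[cbind(i, j)] <- vals
  if (axis == "x") m else t(m)
}
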