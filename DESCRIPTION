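Package: dotscape
Title: Multi-Channel Dot Plots for Multifaceted Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A universal dot-plot engine for long-format tables mixing
    quantitative and qualitative factors. Up to four factors of an
    (x, y) grid are mapped onto dot size, color, text and shape --
    including a quantitative shape glyph (circular sector) suited to
    percentages. Axis levels can be reordered by hierarchical clustering
    on factor-analysis coordinates, with automatic dispatch to principal
    component analysis, multiple correspondence analysis or factor
    analysis of mixed data depending on the column types. Includes a
    summarization adaptor that turns a gene-by-cell expression matrix
    plus cluster labels into percent-of-expressing-cells and
    mean-scaled-expression tables, a deterministic SVG renderer, an
    extensible 'ggplot2' plot object, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    Matrix,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
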