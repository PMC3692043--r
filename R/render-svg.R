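# SVG emission primitives. All numeric attributes go through num(): fixed
# two-decimal formatting, so identical inputs always produce byte-identical
# documents (no locale, font-metric or iteration-order dependence anywhere).

num <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_rect <- function(x, y, w, h, fill, opacity = NULL, stroke = NULL) {
  extra <- ""
  if (!is.null(opacity)) extra <- paste0(extra, sprintf(' fill-opacity="%s"', num(opacity)))
  if (!is.null(stroke)) extra <- paste0(extra, sprintf(' stroke="%s"', stroke))
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          num(x), num(y), num(w), num(h), fill, extra)
}

svg_line <- function(x1, y1, x2, y2, stroke, width = 1) {
  sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          num(x1), num(y1), num(x2), num(y2), stroke, num(width))
}

svg_text <- function(x, y, text, size, fill = "#222222", anchor = "start") {
  sprintf('<text x="%s" y="%s" font-size="%s" font-family="monospace" fill="%s" text-anchor="%s">%s</text>',
          num(x), num(y), num(size), fill, anchor, xml_escape(text))
}

svg_polygon <- function(xs, ys, fill) {
  pts <- paste(paste(num(xs), num(ys), sep = ","), collapse = " ")
  sprintf('<polygon points="%s" fill="%s"/>', pts, fill)
}

svg_group <- function(y, body) {
  c(sprintf('<g transform="translate(0,%s)">', num(y)), body, "</g>")
}

#' Shipped colour palettes
#'
#' Fixed hex palettes keying gene-model features by biotype, variants by
#' consequence type, sequence letters and coverage mismatches by base, and
#' ideogram bands by Giemsa stain. Each palette carries a `default` entry
#' for unknown or empty labels. Any entry can be overridden per track via
#' `track_config(palette = ...)`.
#'
#' @return Named character vector of hex colours.
#' @export
biotype_palette <- function() c(
  protein_coding = "#8f1d1d",
  lncRNA = "#2e7f6f",
  miRNA = "#b8860b",
  pseudogene = "#777777",
  snRNA = "#6a3d9a",
  snoRNA = "#9a6fb8",
  rRNA = "#2a6fbb",
  misc_RNA = "#54778f",
  default = "#444444"
)

#' @rdname biotype_palette
#' @export
consequence_palette <- function() c(
  missense_variant = "#e07b00",
  synonymous_variant = "#2e8b57",
  stop_gained = "#d40000",
  intron_variant = "#3465a4",
  splice_region_variant = "#cc5fcf",
  upstream_gene_variant = "#8f5902",
  downstream_gene_variant = "#7a5fc0",
  intergenic_variant = "#888888",
  default = "#666666"
)

#' @rdname biotype_palette
#' @export
base_palette <- function() c(
  A = "#109648", C = "#255c99", G = "#f7b32b", T = "#d62839",
  N = "#808080", default = "#808080"
)

#' @rdname biotype_palette
#' @export
stain_palette <- function() c(
  gneg = "#ffffff", gpos25 = "#c8c8c8", gpos50 = "#969696",
  gpos75 = "#646464", gpos100 = "#323232", acen = "#b84d4d",
  gvar = "#e0d8e8", stalk = "#7a8ba3", default = "#dddddd"
)
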