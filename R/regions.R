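#' Genomic regions
#'
#' A `gm_region` is a chromosome interval in display coordinates: 1-based,
#' both ends inclusive. It is the universal query key of the toolkit. All
#' user-facing and JSON-exchanged coordinates use this convention (as GFF and
#' VCF do); arithmetic-heavy internals convert to 0-based half-open pairs at
#' a single boundary via [to_internal()] / [to_display()].
#'
#' @param chrom Chromosome name. Compared verbatim everywhere: no "chr"
#'   normalisation is ever applied, because silent renaming corrupts joins
#'   across files.
#' @param start,end 1-based inclusive positions, `start >= 1`, `end >= start`.
#' @return An object of class `gm_region`: a list with fields `chrom`,
#'   `start`, `end`.
#' @examples
#' r <- gm_region("chr7", 100, 200)
#' region_length(r) # 101
#' @export
gm_region <- function(chrom, start, end = start) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    stop_gm("parse", "chromosome name must be a non-empty string")
  start <- as_count(start, "start")
  end <- as_count(end, "end")
  if (start < 1L)
    stop_gm("range", sprintf("start must be >= 1, got %d", start))
  if (end < start)
    stop_gm("range", sprintf("end (%d) precedes start (%d)", end, start))
  structure(list(chrom = chrom, start = start, end = end), class = "gm_region")
}

#' @export
print.gm_region <- function(x, ...) {
  cat("<gm_region> ", format_region(x), "\n", sep = "")
  invisible(x)
}

#' @rdname gm_region
#' @param x A `gm_region`.
#' @export
region_length <- function(x) x$end - x$start + 1L

as_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != trunc(x))
    stop_gm("parse", sprintf("%s must be a single integer, got %s", what, deparse(x)))
  as.integer(x)
}

#' Parse a region string
#'
#' Accepts the navigation-bar grammar `CHROM:START-END`, `CHROM:POS` (a
#' single base: start = end = POS), or a bare `CHROM` (the full chromosome,
#' only when its length is known via `chrom_lengths`). Thousands separators
#' (commas) inside positions are tolerated.
#'
#' @param text Region string.
#' @param chrom_lengths Optional named integer vector of chromosome lengths,
#'   required to resolve a bare chromosome name.
#' @return A [gm_region()].
#' @examples
#' parse_region("chr7:100-200")
#' parse_region("chr7:150")
#' @export
parse_region <- function(text, chrom_lengths = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop_gm("parse", "region text must be a non-empty string")
  text <- trimws(text)
  if (grepl("^[^:]+:[0-9,]+-[0-9,]+$", text)) {
    chrom <- sub(":.*$", "", text)
    pos <- strsplit(sub("^[^:]+:", "", text), "-", fixed = TRUE)[[1L]]
    return(gm_region(chrom, strip_commas(pos[1L]), strip_commas(pos[2L])))
  }
  if (grepl("^[^:]+:[0-9,]+$", text)) {
    chrom <- sub(":.*$", "", text)
    pos <- strip_commas(sub("^[^:]+:", "", text))
    return(gm_region(chrom, pos, pos))
  }
  if (grepl("^[^:[:space:]]+$", text)) {
    if (is.null(chrom_lengths) || is.na(chrom_lengths[text]))
      stop_gm("parse", sprintf(
        "bare chromosome '%s' needs a known length to form a region", text))
    return(gm_region(text, 1L, unname(chrom_lengths[text])))
  }
  bad <- sub("^[^:]*:", "", text)
  stop_gm("parse", sprintf("malformed region '%s' (offending token '%s')", text, bad))
}

strip_commas <- function(x) as.integer(gsub(",", "", x, fixed = TRUE))

#' @rdname parse_region
#' @param region A `gm_region`.
#' @return `format_region()`: the canonical `CHROM:START-END` string;
#'   `parse_region(format_region(r))` is the identity.
#' @export
format_region <- function(region) {
  sprintf("%s:%d-%d", region$chrom, region$start, region$end)
}

#' Do two regions overlap?
#'
#' Closed-interval overlap on the same chromosome (chromosome names compared
#' verbatim). Touching endpoints count as overlap; adjacent intervals do not.
#'
#' @param a,b `gm_region` objects.
#' @return `TRUE` or `FALSE`.
#' @export
regions_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

#' Display/internal coordinate conversion
#'
#' Display coordinates are 1-based inclusive; internal coordinates are
#' 0-based half-open. `to_internal(s, e)` returns `c(s - 1, e)`;
#' `to_display()` inverts it exactly. The half-open length equals the
#' display length.
#'
#' @param display_start,display_end 1-based inclusive coordinates.
#' @return Integer vector `c(start0, end0)` (0-based half-open).
#' @export
to_internal <- function(display_start, display_end) {
  c(as.integer(display_start) - 1L, as.integer(display_end))
}

#' @rdname to_internal
#' @param internal_start,internal_end 0-based half-open coordinates.
#' @export
to_display <- function(internal_start, internal_end) {
  c(as.integer(internal_start) + 1L, as.integer(internal_end))
}

# classed conditions: "parse" -> gm_parse_error, "range" -> gm_range_error etc.
stop_gm <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("gm_", class, "_error"), "gm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_gm <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}
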