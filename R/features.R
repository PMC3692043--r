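FEATURE_TYPES <- c("gene", "transcript", "exon", "variant", "generic")
STRANDS <- c("+", "-", ".")

#' Canonical feature table
#'
#' The unit of exchange across the toolkit: a data.frame (class
#' `gm_features`) with one row per feature and columns
#' `id`, `name`, `chrom`, `start`, `end`, `strand`, `ftype`, `biotype`,
#' `consequence`, `parent`, `attrs`. Coordinates are 1-based inclusive.
#' `strand` is one of `+`, `-`, `.` (`.` = unstranded, suppresses direction
#' glyphs when rendered). `ftype` is one of gene, transcript, exon, variant,
#' generic. `biotype` colours gene-model features; `consequence` colours
#' variants; either may be empty. `parent` links exons to transcripts and
#' transcripts to genes by id. `attrs` is a list column of named character
#' vectors holding any open key/value payload (ref/alt alleles of variants
#' live here).
#'
#' @param id,name,chrom,strand,ftype,biotype,consequence,parent Character
#'   vectors (recycled where length 1).
#' @param start,end Integer vectors, 1-based inclusive, `end >= start`.
#' @param attrs List of named character vectors (or `NULL` entries).
#' @return A `gm_features` data.frame.
#' @export
gm_features <- function(id = character(), name = "", chrom = character(),
                        start = integer(), end = integer(), strand = ".",
                        ftype = "generic", biotype = "", consequence = "",
                        parent = "", attrs = NULL) {
  n <- max(length(id), length(chrom), length(start))
  rep_n <- function(x) {
    x <- as.character(x)
    if (length(x) == n) x else rep_len(x, n)
  }
  start <- as.integer(rep_len(start, n))
  end <- as.integer(rep_len(end, n))
  if (n > 0L && any(end < start))
    stop_gm("range", "feature end precedes start at row %d", which(end < start)[1L])
  ftype <- rep_n(ftype)
  strand <- rep_n(strand)
  if (n > 0L && !all(ftype %in% FEATURE_TYPES))
    stop_gm("parse", "unknown ftype '%s'", setdiff(ftype, FEATURE_TYPES)[1L])
  if (n > 0L && !all(strand %in% STRANDS))
    stop_gm("parse", "unknown strand '%s'", setdiff(strand, STRANDS)[1L])
  if (is.null(attrs)) attrs <- rep(list(NULL), n)
  df <- data.frame(
    id = rep_n(id), name = rep_n(name), chrom = rep_n(chrom),
    start = start, end = end, strand = strand, ftype = ftype,
    biotype = rep_n(biotype), consequence = rep_n(consequence),
    parent = rep_n(parent), stringsAsFactors = FALSE
  )
  df$attrs <- attrs
  class(df) <- c("gm_features", "data.frame")
  df
}

#' @rdname gm_features
#' @export
empty_features <- function() gm_features()

#' Bind feature tables
#' @param ... `gm_features` data.frames.
#' @return A single `gm_features` data.frame.
#' @export
bind_features <- function(...) {
  pieces <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(pieces) == 0L) return(empty_features())
  out <- do.call(rbind, lapply(pieces, function(x) {
    class(x) <- "data.frame"
    x
  }))
  rownames(out) <- NULL
  class(out) <- c("gm_features", "data.frame")
  out
}

#' Keep features overlapping a region
#'
#' Closed-interval overlap on the region's chromosome. Features are returned
#' whole, never clipped: a glyph that pokes past the screen edge must keep
#' its true extent so panning is continuous.
#'
#' @param features A `gm_features` data.frame.
#' @param region A [gm_region()], or `NULL` for no filtering.
#' @return The overlapping subset, input order preserved.
#' @export
filter_overlap <- function(features, region) {
  if (is.null(region) || nrow(features) == 0L) return(features)
  keep <- features$chrom == region$chrom &
    features$start <= region$end & features$end >= region$start
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical feature ordering
#'
#' Sorts by (chrom, start, end, id) with a radix sort, the deterministic
#' order [query()] returns and cache assembly relies on.
#'
#' @param features A [gm_features()] data.frame.
#' @return The sorted table.
#' @export
sort_features <- function(features) {
  if (nrow(features) == 0L) return(features)
  o <- order(features$chrom, features$start, features$end, features$id,
             method = "radix")
  out <- features[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

feature_span <- function(features) features$end - features$start + 1L
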