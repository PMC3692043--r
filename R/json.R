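SCHEMA_VERSION <- "1.0"
JSON_SOURCES <- c("gff", "bed", "vcf", "bam", "inline")
FEATURE_KEYS <- c("id", "name", "chrom", "start", "end", "strand", "ftype",
                  "biotype", "consequence", "parent", "attrs")

#' Serialize features to the JSON exchange document
#'
#' The wire format of the toolkit (schema version "1.0"): an object with
#' `schema_version`, `source` (one of gff, bed, vcf, bam, inline) and
#' `features`, an ordered array of objects with the eleven canonical keys in
#' a fixed order (`id`, `name`, `chrom`, `start`, `end`, `strand`, `ftype`,
#' `biotype`, `consequence`, `parent`, `attrs`). Coordinates are 1-based
#' inclusive. Serialization is canonical: identical inputs yield
#' byte-identical text, and [from_json()] restores every field exactly.
#'
#' @param features A [gm_features()] data.frame.
#' @param source Format tag recorded in the document.
#' @return A single JSON string (no trailing newline).
#' @export
to_json <- function(features, source = "inline") {
  if (!source %in% JSON_SOURCES)
    stop_gm("parse", "unknown source tag '%s'", source)
  rows <- lapply(seq_len(nrow(features)), function(i) {
    a <- features$attrs[[i]]
    if (is.null(a) || length(a) == 0L) {
      a <- structure(list(), names = character())
    } else {
      a <- as.list(a)
    }
    list(
      id = features$id[i], name = features$name[i], chrom = features$chrom[i],
      start = features$start[i], end = features$end[i],
      strand = features$strand[i], ftype = features$ftype[i],
      biotype = features$biotype[i], consequence = features$consequence[i],
      parent = features$parent[i], attrs = a
    )
  })
  doc <- list(schema_version = SCHEMA_VERSION, source = source, features = rows)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

#' @rdname to_json
#' @param text JSON text produced by [to_json()] (or any schema-1.0
#'   document).
#' @return `from_json()`: the [gm_features()] data.frame; the round trip
#'   `from_json(to_json(x))` is the identity.
#' @export
from_json <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    stop_gm("parse", "feature document is missing required key 'schema_version'")
  if (!identical(doc$schema_version, SCHEMA_VERSION))
    stop_gm("parse", "unknown schema_version '%s'", doc$schema_version)
  if (is.null(doc$features))
    stop_gm("parse", "feature document is missing required key 'features'")
  rows <- doc$features
  if (length(rows) == 0L) return(empty_features())
  for (r in rows) {
    missing <- setdiff(FEATURE_KEYS, names(r))
    if (length(missing) > 0L)
      stop_gm("parse", "feature is missing required key '%s'", missing[1L])
  }
  chr <- function(key) vapply(rows, function(r) as.character(r[[key]]), "")
  int <- function(key) vapply(rows, function(r) as.integer(r[[key]]), 0L)
  gm_features(
    id = chr("id"), name = chr("name"), chrom = chr("chrom"),
    start = int("start"), end = int("end"), strand = chr("strand"),
    ftype = chr("ftype"), biotype = chr("biotype"),
    consequence = chr("consequence"), parent = chr("parent"),
    attrs = lapply(rows, function(r) {
      a <- r$attrs
      if (length(a) == 0L) NULL else unlist(lapply(a, as.character))
    })
  )
}
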