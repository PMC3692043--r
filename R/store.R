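#' A chunk-aligned caching store over any region-queryable feature source
#'
#' The store is a pure latency layer: its answers always equal a direct
#' source query, but repeated and adjacent queries are served from a cache
#' of fixed-width chunks, and [prefetch()] can warm the cache for the
#' windows a user is about to pan into. Each chunk owns the features whose
#' start falls in its bin; at query time the bin immediately left of the
#' window is also scanned, and features longer than one chunk are kept in a
#' per-store overflow list consulted on every query, which together
#' guarantee that no overlapping feature is missed. Eviction removes the
#' least recently fetched chunk once `capacity` is exceeded.
#'
#' @param source A function `function(region)` returning a [gm_features()]
#'   data.frame of all features overlapping `region`; called with `NULL` it
#'   should return every feature (only needed when `build_name_index =
#'   TRUE`). See [file_source()].
#' @param chunk_size Chunk width in bp (default 50,000: a few chunks per
#'   screenful at gene-level zoom).
#' @param capacity Maximum cached chunks (default 256).
#' @param chrom_lengths Optional named vector used to clip prefetch windows
#'   at chromosome ends.
#' @param build_name_index Build the case-folded sorted name index needed by
#'   [name_prefix_search()] (requires a full-scan capable source).
#' @return A `gm_store` object (environment).
#' @export
feature_store <- function(source, chunk_size = 50000L, capacity = 256L,
                          chrom_lengths = NULL, build_name_index = FALSE) {
  stopifnot(is.function(source))
  chunk_size <- as_count(chunk_size, "chunk_size")
  capacity <- as_count(capacity, "capacity")
  if (chunk_size < 1L || capacity < 1L)
    stop_gm("range", "chunk_size and capacity must be positive")
  st <- new.env(parent = emptyenv())
  st$source <- source
  st$chunk_size <- chunk_size
  st$capacity <- capacity
  st$chrom_lengths <- chrom_lengths
  st$chunks <- new.env(parent = emptyenv())
  st$long <- new.env(parent = emptyenv()) # id -> single-row gm_features
  st$clock <- 0L
  st$fetches <- 0L
  st$last_region <- NULL
  st$name_index <- NULL
  class(st) <- "gm_store"
  if (build_name_index) {
    all <- source(NULL)
    named <- all[nzchar(all$name), , drop = FALSE]
    idx <- data.frame(
      name = named$name, chrom = named$chrom,
      start = named$start, end = named$end, stringsAsFactors = FALSE
    )
    idx <- idx[order(tolower(idx$name), idx$chrom, idx$start, method = "radix"), ,
               drop = FALSE]
    rownames(idx) <- NULL
    st$name_index <- idx
  }
  st
}

#' @export
print.gm_store <- function(x, ...) {
  cat(sprintf("<gm_store> chunk %d bp, %d/%d chunks cached, %d source fetches\n",
              x$chunk_size, length(ls(x$chunks)), x$capacity, x$fetches))
  invisible(x)
}

#' A region-query function over an annotation file
#'
#' Wraps a GFF/BED/VCF file as the `source` callable a [feature_store()]
#' expects, querying through a [build_index()] chunk-offset index (`NULL`
#' region falls back to a full read).
#'
#' @param path Annotation file, sorted by chromosome then start.
#' @param format `"gff"`, `"bed"` or `"vcf"`.
#' @param info_key Consequence INFO key (VCF).
#' @return A function `function(region = NULL) -> gm_features`.
#' @export
file_source <- function(path, format = c("gff", "bed", "vcf"),
                        info_key = "CSQ_TYPE") {
  format <- match.arg(format)
  idx <- build_index(path, format, info_key = info_key)
  reader <- switch(format,
    gff = function() read_gff(path),
    bed = function() read_bed(path),
    vcf = function() read_vcf(path, info_key = info_key)
  )
  function(region = NULL) {
    if (is.null(region)) reader() else indexed_query(idx, region)
  }
}

#' An in-memory region-query function
#'
#' @param features A [gm_features()] data.frame.
#' @return A function `function(region = NULL) -> gm_features`.
#' @export
memory_source <- function(features) {
  force(features)
  function(region = NULL) filter_overlap(features, region)
}

chunk_key <- function(chrom, bin) paste0(chrom, "\r", bin)

# fetch one chunk from the source (counting it), file it in the cache, and
# return its owned features plus any long features discovered
fetch_chunk <- function(store, chrom, bin) {
  lo <- bin * store$chunk_size + 1L
  hi <- (bin + 1L) * store$chunk_size
  got <- store$source(gm_region(chrom, lo, hi))
  store$fetches <- store$fetches + 1L
  long <- feature_span(got) > store$chunk_size
  if (any(long)) {
    for (i in which(long)) {
      store$long[[got$id[i]]] <- got[i, , drop = FALSE]
    }
  }
  owned <- got[got$start >= lo & got$start <= hi, , drop = FALSE]
  store$clock <- store$clock + 1L
  store$chunks[[chunk_key(chrom, bin)]] <-
    list(features = owned, fetched_at = store$clock)
  evict(store)
  owned
}

evict <- function(store) {
  keys <- ls(store$chunks)
  while (length(keys) > store$capacity) {
    at <- vapply(keys, function(k) store$chunks[[k]]$fetched_at, 0L)
    rm(list = keys[which.min(at)], envir = store$chunks)
    keys <- keys[-which.min(at)]
  }
}

ensure_chunks <- function(store, chrom, bins) {
  pieces <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    cached <- store$chunks[[chunk_key(chrom, bins[i])]]
    pieces[[i]] <- if (is.null(cached))
      fetch_chunk(store, chrom, bins[i]) else cached$features
  }
  pieces
}

#' Query a store for the features overlapping a region
#'
#' Assembles the answer from cached chunks, fetching only the missing ones;
#' an identical repeat query performs zero source fetches. Results are
#' sorted by (chrom, start, end, id) and always equal a direct source query.
#'
#' @param store A [feature_store()].
#' @param region A [gm_region()].
#' @return A [gm_features()] data.frame.
#' @export
query <- function(store, region) {
  stopifnot(inherits(store, "gm_store"))
  bin_lo <- max(0L, (region$start - 1L) %/% store$chunk_size - 1L) # one-bin left extension
  bin_hi <- (region$end - 1L) %/% store$chunk_size
  pieces <- ensure_chunks(store, region$chrom, bin_lo:bin_hi)
  long <- lapply(ls(store$long), function(id) store$long[[id]])
  all <- do.call(bind_features, c(pieces, long))
  hit <- filter_overlap(all, region)
  hit <- hit[!duplicated(hit$id), , drop = FALSE] # long features are also chunk-owned
  store$last_region <- region
  sort_features(hit)
}

#' Warm the cache for the windows adjacent to the last query
#'
#' Fetches the missing chunks of the window(s) of equal width immediately
#' left and/or right of the current window, clipped to the chromosome.
#' Best-effort: failures are logged as warnings, never raised, and prefetch
#' never changes any query result — only latency.
#'
#' @param store A [feature_store()] that has served at least one [query()].
#' @param direction `"left"`, `"right"` or `"both"`.
#' @return The store, invisibly.
#' @export
prefetch <- function(store, direction = c("both", "left", "right")) {
  direction <- match.arg(direction)
  cur <- store$last_region
  if (is.null(cur)) stop_gm("state", "prefetch needs a preceding query")
  w <- region_length(cur)
  windows <- list()
  if (direction %in% c("left", "both") && cur$start > 1L) {
    windows$left <- gm_region(cur$chrom, max(1L, cur$start - w), cur$start - 1L)
  }
  if (direction %in% c("right", "both")) {
    len <- store$chrom_lengths[cur$chrom]
    hi <- if (!is.null(store$chrom_lengths) && !is.na(len))
      min(len, cur$end + w) else cur$end + w
    if (hi > cur$end)
      windows$right <- gm_region(cur$chrom, cur$end + 1L, hi)
  }
  for (win in windows) {
    bins <- ((win$start - 1L) %/% store$chunk_size):((win$end - 1L) %/% store$chunk_size)
    tryCatch(ensure_chunks(store, win$chrom, bins),
             error = function(e) warn_gm("prefetch failed: %s", conditionMessage(e)))
  }
  invisible(store)
}

#' Feature-density histogram over a region
#'
#' Bins features by their start position: `counts[i]` is the number of
#' features whose start `s` satisfies `floor((s - start) / bin_width) = i - 1`,
#' with the last bin closed. Binning by start (not overlap) makes the counts
#' conserve: they always sum to the number of feature starts inside the
#' region. This is the low-zoom representation drawn when individual glyphs
#' would be too many.
#'
#' @param store A [feature_store()] (or anything [query()] accepts).
#' @param region A [gm_region()].
#' @param nbins Number of bins (>= 1). Bin width is `region_length / nbins`
#'   bp and may be fractional.
#' @return A `gm_density` object: list with `region`, `nbins`, `bin_width`,
#'   `counts`.
#' @export
density_histogram <- function(store, region, nbins) {
  nbins <- as_count(nbins, "nbins")
  if (nbins < 1L) stop_gm("range", "nbins must be >= 1")
  feats <- query(store, region)
  density_counts(feats, region, nbins)
}

# binning core shared with the renderer (which already holds the features)
density_counts <- function(features, region, nbins) {
  starts <- features$start[features$chrom == region$chrom &
                             features$start >= region$start &
                             features$start <= region$end]
  bin_width <- region_length(region) / nbins
  idx <- pmin(nbins - 1L, as.integer(floor((starts - region$start) / bin_width)))
  counts <- tabulate(idx + 1L, nbins)
  structure(list(region = region, nbins = nbins, bin_width = bin_width,
                 counts = as.integer(counts)), class = "gm_density")
}

#' @export
print.gm_density <- function(x, ...) {
  cat(sprintf("<gm_density> %s, %d bins of %.1f bp, %d feature starts\n",
              format_region(x$region), x$nbins, x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Gene/transcript name prefix search
#'
#' Case-insensitive prefix lookup over the store's name index (the
#' navigation-bar "type the beginning of a gene name" behaviour). Results
#' are ordered lexicographically by case-folded name.
#'
#' @param store A [feature_store()] built with `build_name_index = TRUE`.
#' @param prefix Non-empty search prefix.
#' @param limit Maximum number of results (default 10).
#' @return A data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
name_prefix_search <- function(store, prefix, limit = 10L) {
  stopifnot(inherits(store, "gm_store"))
  if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix))
    stop_gm("argument", "prefix must be a non-empty string")
  if (is.null(store$name_index))
    stop_gm("state", "store was built without a name index")
  limit <- as_count(limit, "limit")
  idx <- store$name_index
  hit <- startsWith(tolower(idx$name), tolower(prefix))
  out <- idx[hit, , drop = FALSE][seq_len(min(limit, sum(hit))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
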