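RESOURCE_FORMATS <- c(gene = "gff", variant = "vcf", generic = "bed")

#' Load a dataset registry for the region-query service
#'
#' The registry maps dataset labels to resources (`gene`, `variant`,
#' `generic`, `sequence`, `cytoband`) and their backing files, read from a
#' YAML configuration:
#'
#' ```yaml
#' datasets:
#'   mygenome:
#'     gene:     {path: genes.gff,    format: gff}
#'     variant:  {path: variants.vcf, format: vcf}
#'     generic:  {path: features.bed, format: bed}
#'     sequence: {path: genome.fa}
#'     cytoband: {path: cytoBand.txt}
#' ```
#'
#' Relative paths resolve against the YAML file's directory. Every
#' annotation resource is chunk-indexed at load time; a missing or
#' unindexable file fails startup. [data_dir_registry()] builds the same
#' registry directly from a [simulate_dataset()]-style directory without a
#' YAML file.
#'
#' @param path YAML configuration file.
#' @return A `gm_registry` object.
#' @export
load_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L)
    stop_gm("argument", "registry '%s' defines no datasets", path)
  base <- dirname(normalizePath(path))
  reg <- list()
  for (ds in names(cfg$datasets)) {
    reg[[ds]] <- lapply(names(cfg$datasets[[ds]]), function(res) {
      entry <- cfg$datasets[[ds]][[res]]
      p <- entry$path
      if (!file.exists(p)) p <- file.path(base, entry$path)
      build_resource(res, p, entry$format)
    })
    names(reg[[ds]]) <- names(cfg$datasets[[ds]])
  }
  structure(reg, class = "gm_registry")
}

#' @rdname load_registry
#' @param dir Directory holding `genes.gff`, `variants.vcf`, `features.bed`,
#'   `genome.fa`, `cytoBand.txt` (any subset), registered as dataset
#'   `dataset`.
#' @param dataset Dataset label.
#' @export
data_dir_registry <- function(dir, dataset = "local") {
  files <- c(gene = "genes.gff", variant = "variants.vcf",
             generic = "features.bed", sequence = "genome.fa",
             cytoband = "cytoBand.txt")
  present <- files[file.exists(file.path(dir, files))]
  if (length(present) == 0L)
    stop_gm("argument", "no registrable files under '%s'", dir)
  entries <- lapply(names(present), function(res)
    build_resource(res, file.path(dir, present[[res]]),
                   RESOURCE_FORMATS[res]))
  names(entries) <- names(present)
  structure(stats::setNames(list(entries), dataset), class = "gm_registry")
}

build_resource <- function(res, path, format = NULL) {
  if (!file.exists(path)) stop_gm("io", "resource file not found: '%s'", path)
  if (res %in% c("gene", "variant", "generic")) {
    if (is.null(format) || is.na(format)) format <- RESOURCE_FORMATS[[res]]
    list(kind = "features", path = path, format = format,
         index = build_index(path, format))
  } else if (res == "sequence") {
    list(kind = "sequence", path = path, fasta = read_fasta(path))
  } else if (res == "cytoband") {
    list(kind = "cytoband", path = path, bands = read_cytoband(path))
  } else {
    stop_gm("argument", "unknown resource kind '%s'", res)
  }
}

#' @export
print.gm_registry <- function(x, ...) {
  for (ds in names(x))
    cat(sprintf("<gm_registry> %s: %s\n", ds, paste(names(x[[ds]]), collapse = ", ")))
  invisible(x)
}

#' Answer one service request in-process
#'
#' The route table of the service (see [start_service()]), callable without
#' a socket so that every endpoint can be tested and scripted as a plain
#' function call. Routes:
#' \itemize{
#'   \item `GET /api/{dataset}/region/{chrom}:{start}-{end}/{resource}` —
#'     the indexed features overlapping the region as a feature document
#'     (`resource` in `gene`, `variant`, `generic`; `sequence` returns the
#'     bases, `cytoband` the overlapping bands as generic features).
#'   \item `GET /api/{dataset}/region/{...}/histogram?bins=N&source=gene` —
#'     the start-binned density histogram of a feature resource.
#'   \item `GET /api/{dataset}/search?prefix=P&limit=K` — case-insensitive
#'     gene/transcript name prefix search over the `gene` resource.
#' }
#' Unknown datasets/resources give 404, malformed regions or parameters
#' 400, always with a JSON error body. Responses depend only on the request
#' and the registered files.
#'
#' @param registry A `gm_registry`.
#' @param path Request path.
#' @param query Named list/character of query parameters.
#' @return List with `status`, `content_type`, `body` (JSON string).
#' @export
handle_request <- function(registry, path, query = list()) {
  err <- function(status, msg) list(
    status = status, content_type = "application/json",
    body = as.character(jsonlite::toJSON(list(error = msg), auto_unbox = TRUE)))
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  parts <- vapply(parts, utils::URLdecode, "")
  if (length(parts) < 3L || parts[1L] != "api")
    return(err(404L, "not found"))
  ds <- registry[[parts[2L]]]
  if (is.null(ds)) return(err(404L, sprintf("unknown dataset '%s'", parts[2L])))

  if (parts[3L] == "search") {
    prefix <- query$prefix
    if (is.null(prefix) || !nzchar(prefix))
      return(err(400L, "search needs a non-empty 'prefix' parameter"))
    limit <- if (is.null(query$limit)) 10L else
      suppressWarnings(as.integer(query$limit))
    if (is.na(limit) || limit < 1L) return(err(400L, "bad 'limit'"))
    res <- ds$gene
    if (is.null(res)) return(err(404L, "dataset has no 'gene' resource"))
    hits <- search_resource(res, prefix, limit)
    return(list(status = 200L, content_type = "application/json",
                body = as.character(jsonlite::toJSON(hits, auto_unbox = TRUE,
                                                     digits = NA))))
  }

  if (parts[3L] == "region" && length(parts) == 5L) {
    region <- tryCatch(parse_region(parts[4L]), error = function(e) NULL)
    if (is.null(region))
      return(err(400L, sprintf("malformed region '%s'", parts[4L])))
    resource <- parts[5L]

    if (resource == "histogram") {
      bins <- if (is.null(query$bins)) 25L else
        suppressWarnings(as.integer(query$bins))
      if (is.na(bins) || bins < 1L)
        return(err(400L, "'bins' must be a positive integer"))
      src_name <- if (is.null(query$source)) "gene" else query$source
      res <- ds[[src_name]]
      if (is.null(res) || res$kind != "features")
        return(err(404L, sprintf("no feature resource '%s'", src_name)))
      feats <- indexed_query(res$index, region)
      d <- density_counts(feats, region, bins)
      body <- jsonlite::toJSON(list(
        region = format_region(region), nbins = d$nbins,
        bin_width = d$bin_width, counts = d$counts
      ), auto_unbox = TRUE, digits = NA)
      return(list(status = 200L, content_type = "application/json",
                  body = as.character(body)))
    }

    res <- ds[[resource]]
    if (is.null(res))
      return(err(404L, sprintf("unknown resource '%s'", resource)))
    if (res$kind == "features") {
      feats <- indexed_query(res$index, region)
      return(list(status = 200L, content_type = "application/json",
                  body = to_json(feats, source = res$format)))
    }
    if (res$kind == "sequence") {
      seq <- tryCatch(get_sequence(res$fasta, region),
                      error = function(e) NULL)
      if (is.null(seq))
        return(err(400L, sprintf("region %s outside reference", parts[4L])))
      body <- jsonlite::toJSON(list(
        schema_version = SCHEMA_VERSION, source = "inline",
        region = format_region(region), sequence = seq
      ), auto_unbox = TRUE)
      return(list(status = 200L, content_type = "application/json",
                  body = as.character(body)))
    }
    if (res$kind == "cytoband") {
      b <- res$bands
      b <- b[b$chrom == region$chrom & b$start <= region$end &
               b$end >= region$start, , drop = FALSE]
      feats <- gm_features(
        id = paste0("band:", b$chrom, ":", b$name), name = b$name,
        chrom = b$chrom, start = b$start, end = b$end, ftype = "generic",
        attrs = lapply(b$stain, function(s) c(stain = s))
      )
      return(list(status = 200L, content_type = "application/json",
                  body = to_json(feats, source = "inline")))
    }
  }
  err(404L, "not found")
}

search_resource <- function(res, prefix, limit) {
  feats <- switch(res$format,
    gff = read_gff(res$path),
    bed = read_bed(res$path),
    vcf = read_vcf(res$path)
  )
  named <- feats[nzchar(feats$name), , drop = FALSE]
  hit <- named[startsWith(tolower(named$name), tolower(prefix)), , drop = FALSE]
  hit <- hit[order(tolower(hit$name), hit$chrom, hit$start, method = "radix"), ,
             drop = FALSE]
  hit <- hit[seq_len(min(limit, nrow(hit))), , drop = FALSE]
  lapply(seq_len(nrow(hit)), function(i) list(
    name = hit$name[i],
    region = format_region(gm_region(hit$chrom[i], hit$start[i], hit$end[i]))
  ))
}

# wrap a handler response for the wire, gzip-compressing when accepted
encode_response <- function(resp, accept_encoding = "") {
  headers <- list("Content-Type" = resp$content_type)
  body <- charToRaw(resp$body)
  if (grepl("gzip", accept_encoding, fixed = TRUE)) {
    body <- memCompress(body, type = "gzip")
    headers[["Content-Encoding"]] <- "gzip"
  }
  list(status = resp$status, headers = headers, body = body)
}

#' Run the HTTP region-query service
#'
#' Serves the routes of [handle_request()] over HTTP/1.1, compressing JSON
#' bodies with gzip whenever the client advertises `Accept-Encoding: gzip`.
#' The service is stateless: a response depends only on the request and the
#' registered files.
#'
#' @param registry A `gm_registry` ([load_registry()] /
#'   [data_dir_registry()]).
#' @param port TCP port (default 8080).
#' @param host Bind address.
#' @param blocking Run the event loop forever (`TRUE`, for scripts) or
#'   return the server handle (`FALSE`; stop it with
#'   `httpuv::stopServer()`).
#' @return The `httpuv` server handle when `blocking = FALSE`.
#' @export
start_service <- function(registry, port = 8080L, host = "127.0.0.1",
                          blocking = TRUE) {
  stopifnot(inherits(registry, "gm_registry"))
  app <- list(call = function(req) {
    query <- parse_query_string(req$QUERY_STRING)
    resp <- tryCatch(
      handle_request(registry, req$PATH_INFO, query),
      error = function(e) list(status = 500L,
                               content_type = "application/json",
                               body = as.character(jsonlite::toJSON(
                                 list(error = conditionMessage(e)),
                                 auto_unbox = TRUE))))
    encode_response(resp, req$HTTP_ACCEPT_ENCODING %||% "")
  })
  if (blocking) {
    httpuv::runServer(host, as.integer(port), app)
  } else {
    httpuv::startServer(host, as.integer(port), app)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  pairs <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- lapply(pairs, function(p)
    utils::URLdecode(if (length(p) > 1L) p[2L] else ""))
  names(vals) <- vapply(pairs, `[`, "", 1L)
  vals
}
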