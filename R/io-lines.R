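# Record-level parsers shared by the whole-file readers and the byte-offset
# chunk index. Each takes raw data lines (headers already removed) and returns
# a gm_features table; `lineno` carries original line numbers for errors.

GFF_BIOTYPE_KEYS <- c("biotype", "gene_biotype", "transcript_biotype")

is_comment <- function(lines) startsWith(lines, "#") |
  startsWith(lines, "track") | startsWith(lines, "browser")

# Content-derived ids for records that carry none of their own. Line numbers
# would differ between a whole-file scan and an indexed byte-range read, so
# ids are built from coordinates (+ an occurrence counter for duplicates;
# duplicates share a start, hence a bin, hence are always read together).
content_ids <- function(prefix, key) {
  occ <- stats::ave(rep(1L, length(key)), key, FUN = seq_along)
  paste0(prefix, ":", key, ifelse(occ > 1L, paste0("#", occ), ""))
}

parse_bed_lines <- function(lines, lineno = seq_along(lines)) {
  if (length(lines) == 0L) return(empty_features())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 0L)
  if (any(ncol < 3L))
    stop_gm("parse", "BED line %d has fewer than 3 columns",
            lineno[which(ncol < 3L)[1L]])
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "", "")
  s0 <- suppressWarnings(as.integer(col(2)))
  e0 <- suppressWarnings(as.integer(col(3)))
  bad <- is.na(s0) | is.na(e0)
  if (any(bad))
    stop_gm("parse", "BED line %d: non-integer coordinates", lineno[which(bad)[1L]])
  # 0-based half-open in, 1-based inclusive out
  start <- s0 + 1L
  end <- e0
  degenerate <- end < start
  if (any(degenerate)) {
    warn_gm("dropping %d BED record(s) with end <= start (first at line %d)",
            sum(degenerate), lineno[which(degenerate)[1L]])
  }
  keep <- !degenerate
  strand <- col(6)[keep]
  strand[!strand %in% c("+", "-")] <- "."
  chrom <- col(1)[keep]
  name <- col(4)[keep]
  s <- start[keep]
  e <- end[keep]
  gm_features(
    id = content_ids("bed", sprintf("%s:%d-%d:%s", chrom, s, e, name)),
    name = name, chrom = chrom, start = s, end = e,
    strand = strand, ftype = "generic"
  )
}

gff_attr <- function(attr_strings, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regexpr(pat, attr_strings, perl = TRUE)
  out <- rep("", length(attr_strings))
  hit <- m > 0L
  if (any(hit)) {
    frag <- substring(attr_strings[hit], m[hit],
                      m[hit] + attr(m, "match.length")[hit] - 1L)
    out[hit] <- sub(paste0("^(;)?\\s*", key, "="), "", frag)
  }
  out
}

parse_gff_lines <- function(lines, lineno = seq_along(lines)) {
  if (length(lines) == 0L) return(empty_features())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 0L)
  if (any(ncol < 9L))
    stop_gm("parse", "GFF line %d has fewer than 9 columns",
            lineno[which(ncol < 9L)[1L]])
  col <- function(i) vapply(fields, `[`, "", i)
  start <- suppressWarnings(as.integer(col(4)))
  end <- suppressWarnings(as.integer(col(5)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop_gm("parse", "GFF line %d: non-integer coordinates", lineno[which(bad)[1L]])
  type <- col(3)
  ftype <- rep("generic", length(type))
  ftype[type == "gene"] <- "gene"
  ftype[type %in% c("mRNA", "transcript")] <- "transcript"
  ftype[type == "exon"] <- "exon"
  strand <- col(7)
  strand[!strand %in% c("+", "-")] <- "."
  attrs <- col(9)
  id <- gff_attr(attrs, "ID")
  noid <- id == ""
  if (any(noid)) {
    auto <- content_ids("gff", sprintf("%s:%d-%d:%s", col(1), start, end, type))
    id[noid] <- auto[noid]
  }
  biotype <- rep("", length(attrs))
  for (key in GFF_BIOTYPE_KEYS) {
    miss <- biotype == ""
    if (!any(miss)) break
    biotype[miss] <- gff_attr(attrs[miss], key)
  }
  gm_features(
    id = id,
    name = gff_attr(attrs, "Name"),
    chrom = col(1), start = start, end = end,
    strand = strand, ftype = ftype, biotype = biotype,
    parent = gff_attr(attrs, "Parent")
  )
}

parse_vcf_lines <- function(lines, lineno = seq_along(lines),
                            info_key = "CSQ_TYPE") {
  if (length(lines) == 0L) return(empty_features())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, 0L)
  ok <- ncol >= 8L
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "", "")
  pos <- suppressWarnings(as.integer(col(2)))
  ref <- col(4)
  ok <- ok & !is.na(pos) & grepl("^[ACGTNacgtn]+$", ref)
  if (any(!ok))
    warn_gm("skipping %d malformed VCF record(s) (first at line %d)",
            sum(!ok), lineno[which(!ok)[1L]])
  if (!any(ok)) return(empty_features())
  keep <- which(ok)
  pos <- pos[keep]
  ref <- ref[keep]
  alt <- col(5)[keep]
  vid <- col(3)[keep]
  chrom <- col(1)[keep]
  auto <- vid == "." | vid == ""
  if (any(auto)) {
    gen <- content_ids("vcf", sprintf("%s:%d:%s:%s", chrom, pos, ref, alt))
    vid[auto] <- gen[auto]
  }
  info <- col(8)[keep]
  csq <- gff_attr(info, info_key) # same KEY=VALUE;... grammar as GFF col 9
  gm_features(
    id = vid, name = vid, chrom = chrom,
    start = pos, end = pos + nchar(ref) - 1L,
    strand = ".", ftype = "variant", consequence = csq,
    attrs = Map(function(r, a) c(ref = r, alt = a), ref, alt, USE.NAMES = FALSE)
  )
}

# minimal (chrom, start, end) extraction used by the index builder; start/end
# in display coordinates
record_coords <- function(lines, format, lineno, info_key = "CSQ_TYPE") {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  if (format == "bed") {
    start <- suppressWarnings(as.integer(col(2))) + 1L
    end <- suppressWarnings(as.integer(col(3)))
  } else if (format == "gff") {
    start <- suppressWarnings(as.integer(col(4)))
    end <- suppressWarnings(as.integer(col(5)))
  } else if (format == "vcf") {
    start <- suppressWarnings(as.integer(col(2)))
    ref <- col(4)
    end <- start + ifelse(grepl("^[ACGTNacgtn]+$", ref), nchar(ref), 1L) - 1L
  } else {
    stop_gm("parse", "unsupported index format '%s'", format)
  }
  bad <- is.na(start) | is.na(end)
  if (format != "vcf" && any(bad))
    stop_gm("parse", "%s line %d: non-integer coordinates", toupper(format),
            lineno[which(bad)[1L]])
  list(chrom = col(1), start = start, end = end, bad = bad)
}
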