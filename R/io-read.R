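#' Read a BED file into the canonical feature model
#'
#' BED3 to BED6 columns are understood. BED is 0-based half-open on disk;
#' features come back in display coordinates (start = col2 + 1, end = col3),
#' `ftype = "generic"`, name from column 4 when present, strand from column 6.
#' Records with `end <= start` (zero or negative length) are rejected with a
#' warning, never fatally.
#'
#' @param path BED file.
#' @param region Optional [gm_region()]; only overlapping features are
#'   returned (whole, never clipped).
#' @return A [gm_features()] data.frame.
#' @export
read_bed <- function(path, region = NULL) {
  lines <- read_data_lines(path)
  filter_overlap(parse_bed_lines(lines$text, lines$lineno), region)
}

#' Read GFF3 gene models
#'
#' `gene`, `mRNA`/`transcript` and `exon` records map to ftypes gene,
#' transcript and exon; any other type becomes `generic`. `ID`, `Parent` and
#' `Name` attributes are captured; the biotype is taken from the first
#' present of the attribute keys `biotype`, `gene_biotype`,
#' `transcript_biotype`. Parent links are resolved within the file; an exon
#' whose Parent is absent is kept, with a warning about the dangling link.
#'
#' @inheritParams read_bed
#' @return A [gm_features()] data.frame.
#' @export
read_gff <- function(path, region = NULL) {
  lines <- read_data_lines(path)
  feats <- parse_gff_lines(lines$text, lines$lineno)
  dangling <- feats$ftype == "exon" & feats$parent != "" &
    !(feats$parent %in% feats$id)
  if (any(dangling))
    warn_gm("%d exon(s) with Parent not found in file (first: %s)",
            sum(dangling), feats$id[which(dangling)[1L]])
  filter_overlap(feats, region)
}

#' Read a VCF into the canonical feature model
#'
#' Variants become features with `ftype = "variant"`, `start = POS`,
#' `end = POS + nchar(REF) - 1` (so SNVs span one base and deletions span the
#' REF allele), ref/alt alleles in `attrs`, and the consequence label read
#' from one configurable INFO key (default `CSQ_TYPE`, a single token).
#' Annotation-dialect parsing (VEP/SnpEff strings) is deliberately out of
#' scope; the fixture generator writes the same key. A file with no `##`
#' header is rejected; malformed records are skipped with a warning.
#'
#' @inheritParams read_bed
#' @param info_key INFO key holding the consequence label.
#' @return A [gm_features()] data.frame.
#' @export
read_vcf <- function(path, region = NULL, info_key = "CSQ_TYPE") {
  all_lines <- readLines(path)
  if (length(all_lines) == 0L || !any(startsWith(all_lines, "##")))
    stop_gm("parse", "'%s' has no VCF header", path)
  data <- !startsWith(all_lines, "#")
  feats <- parse_vcf_lines(all_lines[data], which(data), info_key = info_key)
  filter_overlap(feats, region)
}

#' Read a UCSC-style cytoband table
#'
#' Five tab-separated columns: chrom, start (0-based), end, band name, stain.
#' Stains outside the Giemsa vocabulary (gneg, gpos25/50/75/100, acen, gvar,
#' stalk) are rejected. Bands of one chromosome must be non-overlapping and
#' sorted.
#'
#' @param path Cytoband file.
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `name`, `stain`.
#' @export
read_cytoband <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stain = character()))
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 0L) < 5L))
    stop_gm("parse", "cytoband line %d has fewer than 5 columns",
            lines$lineno[which(vapply(fields, length, 0L) < 5L)[1L]])
  col <- function(i) vapply(fields, `[`, "", i)
  out <- data.frame(
    chrom = col(1),
    start = as.integer(col(2)) + 1L,
    end = as.integer(col(3)),
    name = col(4),
    stain = col(5),
    stringsAsFactors = FALSE
  )
  known <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100", "acen", "gvar", "stalk")
  if (!all(out$stain %in% known))
    stop_gm("parse", "unknown stain '%s'", setdiff(out$stain, known)[1L])
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, ]
    if (is.unsorted(b$start) || any(b$start[-1L] <= b$end[-nrow(b)]))
      stop_gm("range", "cytobands of %s are overlapping or unsorted", ch)
  }
  out
}

#' Read a FASTA reference
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by sequence name (text up to
#'   the first whitespace of each header).
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  dna
}

#' Extract the bases of a region from a reference
#'
#' @param fasta A `DNAStringSet` from [read_fasta()] or a FASTA path.
#' @param region A [gm_region()]; must lie within the sequence.
#' @return A single upper-case character string of length `region_length(region)`.
#' @export
get_sequence <- function(fasta, region) {
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  if (!region$chrom %in% names(fasta))
    stop_gm("range", "chromosome '%s' not in reference", region$chrom)
  len <- length(fasta[[region$chrom]])
  if (region$end > len)
    stop_gm("range", "region end %d beyond %s length %d",
            region$end, region$chrom, len)
  toupper(as.character(Biostrings::subseq(fasta[[region$chrom]],
                                          region$start, region$end)))
}

# data lines of a text format file, with their original line numbers
read_data_lines <- function(path) {
  if (!file.exists(path))
    stop_gm("io", "file not found: '%s'", path)
  lines <- readLines(path)
  keep <- !is_comment(lines) & nzchar(lines)
  list(text = lines[keep], lineno = which(keep))
}
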