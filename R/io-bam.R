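#' Per-base coverage and mismatch counts from a BAM file
#'
#' Computes, for every position of `region`, the number of reads whose
#' aligned bases cover it, and how many of those bases disagree with the
#' reference, split by alternate base. Pileup semantics follow the usual
#' browser convention: only reference-aligned read bases (CIGAR `M`, `=`,
#' `X`) contribute depth; deletions (`D`) and splice gaps (`N`) leave a gap;
#' soft- and hard-clipped bases never count.
#'
#' @param path Coordinate-sorted BAM with a `.bai` index next to it.
#' @param region A [gm_region()]. A region extending past the reference end
#'   is clipped with a warning.
#' @param fasta Optional reference ([read_fasta()] result or FASTA path);
#'   required for mismatch calls, depth-only without it.
#' @return A `gm_coverage` object: list with `region`, `depth` (integer
#'   vector over the region) and `mismatch` (5 x length integer matrix, rows
#'   A, C, G, T, N — read bases differing from the reference at each
#'   position; all zero when `fasta` is absent).
#' @export
bam_coverage <- function(path, region, fasta = NULL) {
  if (!file.exists(path)) stop_gm("io", "BAM not found: '%s'", path)
  bai <- paste0(path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", path)
  if (!file.exists(bai) && !file.exists(bai2))
    stop_gm("io", paste0(
      "no index for '%s'; create one with Rsamtools::indexBam() ",
      "or `samtools index`"), path)

  targets <- Rsamtools::scanBamHeader(path)[[1L]]$targets
  tlen <- targets[region$chrom]
  if (is.na(tlen))
    stop_gm("range", "chromosome '%s' not in BAM header", region$chrom)
  if (region$end > tlen) {
    warn_gm("region end %d clipped to %s length %d", region$end, region$chrom, tlen)
    region <- gm_region(region$chrom, min(region$start, tlen), tlen)
  }

  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(region$chrom,
                                   IRanges::IRanges(region$start, region$end)),
    what = c("pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  hits <- Rsamtools::scanBam(path, param = param)[[1L]]

  L <- region_length(region)
  depth <- integer(L)
  mism <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(c("A", "C", "G", "T", "N")))
  ref <- if (!is.null(fasta))
    strsplit(get_sequence(fasta, region), "")[[1L]] else NULL

  seqs <- as.character(hits$seq)
  for (i in seq_along(hits$pos)) {
    walk <- cigar_walk(hits$cigar[i], hits$pos[i])
    if (length(walk$ref_pos) == 0L) next
    inside <- walk$ref_pos >= region$start & walk$ref_pos <= region$end
    if (!any(inside)) next
    off <- walk$ref_pos[inside] - region$start + 1L
    depth[off] <- depth[off] + 1L
    if (!is.null(ref)) {
      bases <- toupper(substring(seqs[i], walk$query_pos[inside],
                                 walk$query_pos[inside]))
      differs <- bases != ref[off] & bases %in% rownames(mism)
      for (j in which(differs)) {
        mism[bases[j], off[j]] <- mism[bases[j], off[j]] + 1L
      }
    }
  }
  structure(list(region = region, depth = depth, mismatch = mism),
            class = "gm_coverage")
}

#' @export
print.gm_coverage <- function(x, ...) {
  cat(sprintf("<gm_coverage> %s  mean depth %.2f  max %d  mismatching bases %d\n",
              format_region(x$region), mean(x$depth), max(x$depth, 0L),
              sum(x$mismatch)))
  invisible(x)
}

# aligned (M/=/X) base coordinates of one read: parallel vectors of reference
# position and 1-based query position. I/S consume query; D/N consume
# reference; H/P consume neither.
cigar_walk <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substring(ops, nchar(ops), nchar(ops))
  ref_pos <- integer(0)
  query_pos <- integer(0)
  r <- pos
  q <- 1L
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, seq.int(r, length.out = len[k]))
      query_pos <- c(query_pos, seq.int(q, length.out = len[k]))
      r <- r + len[k]
      q <- q + len[k]
    } else if (op[k] %in% c("I", "S")) {
      q <- q + len[k]
    } else if (op[k] %in% c("D", "N")) {
      r <- r + len[k]
    } # H, P: nothing
  }
  list(ref_pos = ref_pos, query_pos = query_pos)
}

# reference span consumed by a CIGAR (sum of M/D/N/=/X lengths)
cigar_ref_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substring(ops, nchar(ops), nchar(ops))
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}
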