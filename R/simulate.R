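#' Configuration of the synthetic fixture generator
#'
#' Defines a small, fully seeded synthetic dataset exercising every input
#' the toolkit reads: a random genome, a nested gene/transcript/exon
#' annotation with sampled biotypes, annotated variants, uniformly placed
#' error-bearing reads and a cytoband table. Defaults describe a desk-scale
#' study: one 100 kb chromosome, 20 genes, 200 variants, 100 bp reads at
#' 10x mean coverage with a 1% per-base error rate. Identical
#' configurations produce byte-identical output trees.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Genes per chromosome, placed without overlap by rejection
#'   sampling (at most `10 * n_genes` attempts, then a loud failure —
#'   lower the density rather than silently dropping genes).
#' @param gene_length Integer range `c(min, max)` of gene locus lengths in
#'   bp. The default keeps gene occupancy near 30% of the default
#'   chromosome so rejection sampling terminates comfortably.
#' @param transcripts_per_gene,exons_per_transcript Integer ranges
#'   `c(min, max)` sampled per gene/transcript.
#' @param biotype_freq,consequence_freq Named sampling frequencies (must sum
#'   to 1) for gene biotypes and variant consequence labels.
#' @param n_variants Variants per chromosome (90% SNVs, 10% short
#'   deletions), REF always matching the genome.
#' @param read_length,mean_coverage,read_error_rate Read geometry: read
#'   count per chromosome is `round(mean_coverage * chrom_length /
#'   read_length)`; bases are copied from the genome and then corrupted at
#'   `read_error_rate` per base.
#' @param n_bed_features Generic BED features per chromosome.
#' @param info_key INFO key the consequence label is written to in the VCF.
#' @return A `gm_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 100000L,
                       n_genes = 20L,
                       gene_length = c(500L, 2500L),
                       transcripts_per_gene = c(1L, 3L),
                       exons_per_transcript = c(2L, 6L),
                       biotype_freq = c(protein_coding = 0.7, lncRNA = 0.15,
                                        pseudogene = 0.1, miRNA = 0.05),
                       n_variants = 200L,
                       consequence_freq = c(intron_variant = 0.3,
                                            missense_variant = 0.2,
                                            synonymous_variant = 0.2,
                                            upstream_gene_variant = 0.15,
                                            intergenic_variant = 0.1,
                                            stop_gained = 0.05),
                       read_length = 100L,
                       mean_coverage = 10,
                       read_error_rate = 0.01,
                       n_bed_features = 50L,
                       info_key = "CSQ_TYPE") {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              exons_per_transcript = as.integer(exons_per_transcript),
              biotype_freq = biotype_freq, n_variants = as.integer(n_variants),
              consequence_freq = consequence_freq,
              read_length = as.integer(read_length),
              mean_coverage = mean_coverage,
              read_error_rate = read_error_rate,
              n_bed_features = as.integer(n_bed_features),
              info_key = info_key)
  if (cfg$chrom_length < 1L) stop_gm("argument", "chrom_length must be positive")
  if (any(c(cfg$n_chroms, cfg$n_genes, cfg$n_variants, cfg$n_bed_features) < 0L))
    stop_gm("argument", "counts must be >= 0")
  for (f in list(cfg$biotype_freq, cfg$consequence_freq))
    if (abs(sum(f) - 1) > 1e-9)
      stop_gm("argument", "sampling frequencies must sum to 1")
  class(cfg) <- "gm_sim_config"
  cfg
}

#' Generate the synthetic dataset
#'
#' Writes, under `out_dir`: `genome.fa` (uniform-random A/C/G/T),
#' `genes.gff` (non-overlapping gene loci with nested transcript/exon
#' records and sampled biotypes), `features.bed`, `variants.vcf`
#' (consequence written to the configured INFO key; REF matches the
#' genome), `reads.sam` plus the converted, coordinate-sorted and indexed
#' `reads.bam`/`.bai` (all-M alignments whose bases match the genome except
#' for the simulated errors), and `cytoBand.txt` (bands partitioning each
#' chromosome, with an acen pair in the middle). All files are mutually
#' consistent and byte-reproducible under the seed. The caller's RNG state
#' is left untouched.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of the written file paths, invisibly.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "gm_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  chroms <- paste0("chrS", seq_len(config$n_chroms))
  L <- config$chrom_length
  genome <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(genome) <- chroms

  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    gff = file.path(out_dir, "genes.gff"),
    bed = file.path(out_dir, "features.bed"),
    vcf = file.path(out_dir, "variants.vcf"),
    sam = file.path(out_dir, "reads.sam"),
    bam = file.path(out_dir, "reads.bam"),
    cytoband = file.path(out_dir, "cytoBand.txt")
  )

  fa <- unlist(lapply(chroms, function(ch) {
    seq <- paste(genome[[ch]], collapse = "")
    c(paste0(">", ch),
      substring(seq, seq(1L, L, 60L), pmin(seq(1L, L, 60L) + 59L, L)))
  }))
  writeLines(fa, paths$fasta)

  gff <- c("##gff-version 3")
  bed <- character(0)
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence type\">",
                   config$info_key),
           unlist(lapply(chroms, function(ch)
             sprintf("##contig=<ID=%s,length=%d>", ch, L))),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           unlist(lapply(chroms, function(ch)
             sprintf("@SQ\tSN:%s\tLN:%d", ch, L))))
  cyto <- character(0)

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    gff <- c(gff, sim_genes(config, ch, ci))
    bed <- c(bed, sim_bed(config, ch, ci))
    vcf <- c(vcf, sim_variants(config, ch, genome[[ch]]))
    sam <- c(sam, sim_reads(config, ch, genome[[ch]]))
    cyto <- c(cyto, sim_cytobands(ch, L))
  }
  writeLines(gff, paths$gff)
  writeLines(bed, paths$bed)
  writeLines(vcf, paths$vcf)
  writeLines(sam, paths$sam)
  writeLines(cyto, paths$cytoband)

  Rsamtools::asBam(paths$sam, sub("\\.bam$", "", paths$bam),
                   overwrite = TRUE, indexDestination = TRUE)
  invisible(paths)
}

sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else
  sample(seq.int(r[1L], r[2L]), 1L)

sim_genes <- function(config, ch, ci) {
  L <- config$chrom_length
  lines <- character(0)
  placed <- matrix(numeric(0), ncol = 2L)
  attempts <- 0L
  g <- 0L
  while (g < config$n_genes) {
    attempts <- attempts + 1L
    if (attempts > 10L * config$n_genes)
      stop_gm("state", "could not place %d non-overlapping genes on %s",
              config$n_genes, ch)
    glen <- sample_range(config$gene_length)
    if (glen >= L) glen <- max(1L, L %/% 10L)
    gstart <- sample.int(L - glen, 1L)
    gend <- gstart + glen - 1L
    if (nrow(placed) > 0L &&
        any(gstart <= placed[, 2L] & gend >= placed[, 1L])) next
    placed <- rbind(placed, c(gstart, gend))
    g <- g + 1L
    gid <- sprintf("GENE%d_%03d", ci, g)
    gname <- paste0(paste(sample(LETTERS, 3L, replace = TRUE), collapse = ""),
                    g)
    strand <- sample(c("+", "-"), 1L)
    biotype <- sample(names(config$biotype_freq), 1L,
                      prob = unname(config$biotype_freq))
    lines <- c(lines, sprintf(
      "%s\tgmaps_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
      ch, gstart, gend, strand, gid, gname, biotype))
    n_tx <- sample_range(config$transcripts_per_gene)
    for (t in seq_len(n_tx)) {
      tid <- sprintf("%s.t%d", gid, t)
      tname <- sprintf("%s-%02d", gname, t)
      # transcript occupies a sub-interval of the gene
      tstart <- gstart + sample.int(max(1L, glen %/% 10L), 1L) - 1L
      tend <- gend - sample.int(max(1L, glen %/% 10L), 1L) + 1L
      if (tend <= tstart) { tstart <- gstart; tend <- gend }
      lines <- c(lines, sprintf(
        "%s\tgmaps_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Parent=%s;biotype=%s",
        ch, tstart, tend, strand, tid, tname, gid, biotype))
      n_ex <- sample_range(config$exons_per_transcript)
      tlen <- tend - tstart + 1L
      n_ex <- min(n_ex, max(1L, tlen %/% 2L))
      cuts <- sort(sample.int(tlen, 2L * n_ex))
      for (e in seq_len(n_ex)) {
        lines <- c(lines, sprintf(
          "%s\tgmaps_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          ch, tstart + cuts[2L * e - 1L] - 1L, tstart + cuts[2L * e] - 1L,
          strand, tid, e, tid))
      }
    }
  }
  # GFF written feature-block-wise is already sorted by gene start? No:
  # genes are placed in random order; sort records by start for the index.
  sort_gff_lines(lines)
}

sort_gff_lines <- function(lines) {
  if (length(lines) == 0L) return(lines)
  start <- as.integer(vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 4L))
  lines[order(start, seq_along(lines), method = "radix")]
}

sim_bed <- function(config, ch, ci) {
  if (config$n_bed_features == 0L) return(character(0))
  L <- config$chrom_length
  len <- sample(50:2000, config$n_bed_features, replace = TRUE)
  start0 <- vapply(len, function(l) sample.int(L - l, 1L) - 1L, 0L)
  lines <- sprintf("%s\t%d\t%d\tregion%d_%03d\t%d\t%s",
                   ch, start0, start0 + len, ci,
                   seq_len(config$n_bed_features),
                   sample(0:1000, config$n_bed_features, replace = TRUE),
                   sample(c("+", "-", "."), config$n_bed_features, replace = TRUE))
  lines[order(start0, seq_along(lines), method = "radix")]
}

sim_variants <- function(config, ch, genome) {
  if (config$n_variants == 0L) return(character(0))
  L <- config$chrom_length
  pos <- sort(sample.int(L - 5L, config$n_variants))
  csq <- sample(names(config$consequence_freq), config$n_variants,
                replace = TRUE, prob = unname(config$consequence_freq))
  is_del <- stats::runif(config$n_variants) < 0.1
  lines <- character(config$n_variants)
  for (i in seq_len(config$n_variants)) {
    if (is_del[i]) {
      dlen <- sample(2:3, 1L)
      ref <- paste(genome[pos[i]:(pos[i] + dlen)], collapse = "")
      alt <- genome[pos[i]]
    } else {
      ref <- genome[pos[i]]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    }
    lines[i] <- sprintf("%s\t%d\trs_sim%d\t%s\t%s\t99\tPASS\t%s=%s",
                        ch, pos[i], i, ref, alt, config$info_key, csq[i])
  }
  lines
}

sim_reads <- function(config, ch, genome) {
  L <- config$chrom_length
  rl <- config$read_length
  n_reads <- as.integer(round(config$mean_coverage * L / rl))
  if (n_reads == 0L) return(character(0))
  pos <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
  qual <- strrep("I", rl)
  lines <- character(n_reads)
  for (i in seq_len(n_reads)) {
    bases <- genome[pos[i]:(pos[i] + rl - 1L)]
    err <- which(stats::runif(rl) < config$read_error_rate)
    for (e in err) bases[e] <- sample(setdiff(c("A", "C", "G", "T"), bases[e]), 1L)
    lines[i] <- sprintf("sim_read_%s_%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                        ch, i, ch, pos[i], rl, paste(bases, collapse = ""), qual)
  }
  lines
}

sim_cytobands <- function(ch, L) {
  # eight bands partitioning the chromosome, an acen pair around the middle
  stains <- c("gneg", "gpos25", "gpos75", "acen", "acen", "gpos100", "gvar", "gneg")
  edges <- round(seq(0L, L, length.out = length(stains) + 1L))
  sprintf("%s\t%d\t%d\t%s%d\t%s", ch, edges[-length(edges)], edges[-1L],
          ifelse(seq_along(stains) <= 4L, "p", "q"), seq_along(stains), stains)
}

#' Validate the mutual consistency of a generated dataset
#'
#' Checks the cross-file guarantees the generator promises: every VCF REF
#' allele matches the genome at its position, and read bases agree with the
#' genome at all non-error positions (i.e. the observed per-read mismatch
#' fraction stays near the configured error rate).
#'
#' @param paths The list returned by [simulate_dataset()].
#' @param max_mismatch_rate Maximum tolerated overall mismatch fraction.
#' @return `TRUE`, invisibly; errors describe the first inconsistency.
#' @export
validate_dataset <- function(paths, max_mismatch_rate = 0.05) {
  fasta <- read_fasta(paths$fasta)
  vcf <- read_vcf(paths$vcf)
  for (i in seq_len(nrow(vcf))) {
    ref <- vcf$attrs[[i]][["ref"]]
    seen <- get_sequence(fasta, gm_region(vcf$chrom[i], vcf$start[i], vcf$end[i]))
    if (!identical(toupper(ref), seen))
      stop_gm("state", "VCF REF '%s' at %s:%d does not match genome '%s'",
              ref, vcf$chrom[i], vcf$start[i], seen)
  }
  for (ch in names(fasta)) {
    len <- length(fasta[[ch]])
    cov <- bam_coverage(paths$bam, gm_region(ch, 1L, len), fasta = fasta)
    aligned <- sum(cov$depth)
    if (aligned > 0L && sum(cov$mismatch) / aligned > max_mismatch_rate)
      stop_gm("state", "mismatch rate %.3f on %s exceeds %.3f",
              sum(cov$mismatch) / aligned, ch, max_mismatch_rate)
  }
  invisible(TRUE)
}
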