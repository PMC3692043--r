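# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code at test time; nothing binary is stored.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# one shared synthetic dataset per test run (desk-scale defaults)
sim_fixture_cache <- new.env()
sim_fixture <- function() {
  if (is.null(sim_fixture_cache$paths)) {
    dir <- file.path(tempdir(), "gm_sim_fixture")
    sim_fixture_cache$paths <- simulate_dataset(sim_config(seed = 20130608L), dir)
    sim_fixture_cache$chrom_length <- 100000L
  }
  sim_fixture_cache$paths
}

# random feature tables for property-style tests
rand_features <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                          max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  gm_features(
    id = sprintf("f%03d", seq_len(n)),
    name = ifelse(stats::runif(n) < 0.5, sprintf("name%d", seq_len(n)), ""),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len - 1L,
    strand = sample(c("+", "-", "."), n, replace = TRUE),
    ftype = sample(c("generic", "variant", "gene"), n, replace = TRUE),
    biotype = sample(c("protein_coding", "lncRNA", ""), n, replace = TRUE),
    consequence = sample(c("missense_variant", ""), n, replace = TRUE),
    attrs = lapply(seq_len(n), function(i)
      if (i %% 3L == 0L) c(ref = "A", alt = "G", note = paste0("x", i)) else NULL)
  )
}

rand_region <- function(chroms = "chrS1", max_pos = 100000L, max_len = 20000L) {
  s <- sample.int(max_pos, 1L)
  gm_region(sample(chroms, 1L), s, min(max_pos, s + sample.int(max_len, 1L) - 1L))
}

# brute-force overlap oracle: per-base membership on small intervals
overlap_by_membership <- function(a, b) {
  a$chrom == b$chrom && length(intersect(seq(a$start, a$end), seq(b$start, b$end))) > 0L
}

# sweep-line maximum overlap depth of half-open pixel intervals [x0, x1)
sweep_depth <- function(x0, x1) {
  if (length(x0) == 0L) return(0L)
  ev <- rbind(data.frame(x = x0, d = 1L), data.frame(x = x1, d = -1L))
  ev <- ev[order(ev$x, ev$d), ] # closings first at ties: half-open semantics
  max(cumsum(ev$d))
}

# naive per-read, per-base depth/mismatch oracle reading the SAM text
# directly (independent of the BAM path and of cigar arithmetic in the
# package: the generator only emits all-M alignments)
sam_coverage_oracle <- function(sam_path, region, fasta = NULL) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  depth <- integer(region_length(region))
  mism <- matrix(0L, 5L, region_length(region),
                 dimnames = list(c("A", "C", "G", "T", "N")))
  ref <- if (!is.null(fasta))
    strsplit(get_sequence(fasta, region), "")[[1L]] else NULL
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[3L] != region$chrom) next
    pos <- as.integer(f[4L])
    stopifnot(grepl("^[0-9]+M$", f[6L]))
    rl <- as.integer(sub("M$", "", f[6L]))
    bases <- strsplit(f[10L], "")[[1L]]
    for (k in seq_len(rl)) {
      p <- pos + k - 1L
      if (p < region$start || p > region$end) next
      off <- p - region$start + 1L
      depth[off] <- depth[off] + 1L
      if (!is.null(ref) && bases[k] != ref[off] && bases[k] %in% rownames(mism))
        mism[bases[k], off] <- mism[bases[k], off] + 1L
    }
  }
  list(depth = depth, mismatch = mism)
}

# extract rect geometry from an SVG document
svg_rects <- function(svg_text) {
  doc <- xml2::read_xml(svg_text)
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='rect']")
  data.frame(
    x = as.numeric(xml2::xml_attr(nodes, "x")),
    y = as.numeric(xml2::xml_attr(nodes, "y")),
    w = as.numeric(xml2::xml_attr(nodes, "width")),
    h = as.numeric(xml2::xml_attr(nodes, "height")),
    fill = xml2::xml_attr(nodes, "fill"),
    stringsAsFactors = FALSE
  )
}

# a tiny hand-written gene locus: gene -> 2 transcripts -> exons
toy_gff_lines <- function() c(
  "##gff-version 3",
  "chr1\ttoy\tgene\t1000\t5000\t.\t+\t.\tID=g1;Name=BRCA2;biotype=protein_coding",
  "chr1\ttoy\tmRNA\t1000\t5000\t.\t+\t.\tID=t1;Name=BRCA2-01;Parent=g1;biotype=protein_coding",
  "chr1\ttoy\texon\t1000\t1500\t.\t+\t.\tID=t1.e1;Parent=t1",
  "chr1\ttoy\texon\t2000\t2600\t.\t+\t.\tID=t1.e2;Parent=t1",
  "chr1\ttoy\texon\t4400\t5000\t.\t+\t.\tID=t1.e3;Parent=t1",
  "chr1\ttoy\tmRNA\t1200\t4800\t.\t+\t.\tID=t2;Name=BRCA2-02;Parent=g1;biotype=protein_coding",
  "chr1\ttoy\texon\t1200\t1600\t.\t+\t.\tID=t2.e1;Parent=t2",
  "chr1\ttoy\texon\t4000\t4800\t.\t+\t.\tID=t2.e2;Parent=t2",
  "chr1\ttoy\tgene\t7000\t8000\t.\t-\t.\tID=g2;Name=BRAF;biotype=lncRNA",
  "chr1\ttoy\tmRNA\t7000\t8000\t.\t-\t.\tID=t3;Name=BRAF-01;Parent=g2;biotype=lncRNA",
  "chr1\ttoy\texon\t7000\t8000\t.\t-\t.\tID=t3.e1;Parent=t3",
  "chr1\ttoy\tgene\t9000\t9500\t.\t+\t.\tID=g3;Name=TP53;biotype=protein_coding"
)

toy_vcf_lines <- function() c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=CSQ_TYPE,Number=1,Type=String,Description=\"Consequence\">",
  "##contig=<ID=chr1,length=100000>",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
  "chr1\t100\trs1\tA\tG\t50\tPASS\tCSQ_TYPE=missense_variant",
  "chr1\t200\trs2\tACG\tA\t50\tPASS\tCSQ_TYPE=stop_gained",
  "chr1\t300\t.\tT\tC\t50\tPASS\tDP=10",
  "chr1\t400\trs4\tG\tT\t50\tPASS\tCSQ_TYPE=synonymous_variant"
)
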