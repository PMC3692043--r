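test_that("level of detail follows zoom and feature count", {
  cfg <- render_config()
  expect_identical(choose_lod("sequence", 0.05, config = cfg), "sequence")
  expect_identical(choose_lod("sequence", 0.5, config = cfg), "blank")
  expect_identical(choose_lod("gene", 10, 50L, cfg), "glyphs")
  expect_identical(choose_lod("gene", 10, 10000L, cfg), "histogram")
  expect_identical(choose_lod("gene", 5000, 50L, cfg), "histogram")
  expect_error(choose_lod("gene", 0, 1L, cfg), class = "gm_argument_error")
})

test_that("LOD is monotone in bp_per_px for a fixed feature count", {
  cfg <- render_config()
  ladder <- c(0.01, 0.1, 1, 10, 100, 1000, 1001, 1e5)
  for (count in c(10L, 1999L, 2001L)) {
    modes <- vapply(ladder, function(b) choose_lod("feature", b, count, cfg), "")
    rank <- c(glyphs = 1L, histogram = 2L)
    expect_false(is.unsorted(rank[modes]))
  }
})

test_that("row packing is greedy first-fit and optimal at gap zero", {
  expect_identical(pack_rows(c(0, 20, 40), c(10, 30, 50)), c(0L, 0L, 0L))
  expect_identical(pack_rows(c(0, 5, 8), c(10, 12, 20)), c(0L, 1L, 2L))
  # touching glyphs share a row at gap 0 but split with a gap
  expect_identical(pack_rows(c(0, 10), c(10, 20), gap_px = 0), c(0L, 0L))
  expect_identical(pack_rows(c(0, 10), c(10, 20), gap_px = 2), c(0L, 1L))
  expect_identical(pack_rows(numeric(0), numeric(0)), integer(0))
  expect_error(pack_rows(5, 4), class = "gm_argument_error")
})

test_that("rows used equal the sweep-line maximum overlap depth", {
  set.seed(701)
  for (rep in 1:20) {
    n <- sample(10:50, 1L)
    x0 <- stats::runif(n, 0, 500)
    x1 <- x0 + stats::runif(n, 1, 80)
    rows <- pack_rows(x0, x1, gap_px = 0)
    expect_identical(max(rows) + 1L, sweep_depth(x0, x1))
    # within-row non-overlap invariant
    for (r in unique(rows)) {
      in_row <- which(rows == r)
      o <- order(x0[in_row])
      starts <- x0[in_row][o]
      ends <- x1[in_row][o]
      if (length(o) > 1L) expect_true(all(starts[-1L] >= ends[-length(ends)]))
    }
  }
})

test_that("colours key off biotype for gene models and consequence for variants", {
  gene <- gm_features(id = "g", chrom = "c", start = 1L, end = 10L,
                      ftype = "gene", biotype = "protein_coding")
  expect_identical(color_for(gene), unname(biotype_palette()["protein_coding"]))
  variant <- gm_features(id = "v", chrom = "c", start = 1L, end = 1L,
                         ftype = "variant", consequence = "stop_gained")
  expect_identical(color_for(variant), unname(consequence_palette()["stop_gained"]))
  unknown <- gm_features(id = "u", chrom = "c", start = 1L, end = 2L,
                         ftype = "gene", biotype = "martian_RNA")
  expect_identical(color_for(unknown), unname(biotype_palette()["default"]))
  blank <- gm_features(id = "b", chrom = "c", start = 1L, end = 2L, ftype = "gene")
  expect_identical(color_for(blank), unname(biotype_palette()["default"]))
  expect_identical(color_for(gene), color_for(gene))
  expect_error(color_for(gene, c(protein_coding = "#112233")),
               class = "gm_argument_error")
})

test_that("an empty region still renders a complete, well-formed document", {
  svg <- render(list(track_config("genes", "gene", empty_features()),
                     track_config("vars", "variant", empty_features())),
                gm_region("chr1", 1000, 2000), 800)
  doc <- xml2::read_xml(svg)
  expect_identical(xml2::xml_name(doc), "svg")
  text <- paste(xml2::xml_text(
    xml2::xml_find_all(doc, "//*[local-name()='text']")), collapse = " ")
  expect_match(text, "Genes")          # legend titles
  expect_match(text, "Variants")
  expect_match(text, "protein_coding") # legend entries
  expect_match(text, "chr1:1000-2000") # status line
  expect_match(text, "1,200")          # ruler tick label
})

test_that("rendering is deterministic and geometry stays inside the canvas", {
  path <- write_lines_tmp(toy_gff_lines(), ".gff")
  feats <- read_gff(path)
  tracks <- list(track_config("genes", "gene", feats))
  region <- gm_region("chr1", 500, 9800)
  a <- render(tracks, region, 1000)
  b <- render(tracks, region, 1000)
  expect_identical(a, b)
  rects <- svg_rects(a)
  expect_true(all(rects$x >= 0 - 1e-9))
  expect_true(all(rects$x + rects$w <= 1000 + 1e-9))
  # x position of a feature start matches (start - region.start) / bp_per_px
  bpp <- region_length(region) / 1000
  expected_x <- (1000 - region$start) / bpp # first exon of t1 starts at 1000
  expect_true(any(abs(rects$x - expected_x) < 0.01))
})

test_that("overlapping transcripts land on distinct packed rows", {
  path <- write_lines_tmp(toy_gff_lines(), ".gff")
  feats <- read_gff(path)
  svg <- render(list(track_config("genes", "gene", feats, label_visible = FALSE)),
                gm_region("chr1", 900, 5100), 1000)
  rects <- svg_rects(svg)
  pal <- biotype_palette()
  gh <- render_config()$glyph_height # excludes the legend swatches
  exon_rows <- sort(unique(
    rects$y[rects$fill == pal[["protein_coding"]] & rects$h == gh]))
  expect_identical(length(exon_rows), 2L) # t1 and t2 overlap -> two rows
})

test_that("feature tracks above the glyph limits fall back to a histogram", {
  set.seed(702)
  many <- rand_features(3000L, chroms = "chr1", max_pos = 9000L)
  svg <- render(list(track_config("dense", "feature", many)),
                gm_region("chr1", 1, 10000), 500)
  doc <- xml2::read_xml(svg)
  text <- paste(xml2::xml_text(
    xml2::xml_find_all(doc, "//*[local-name()='text']")), collapse = " ")
  expect_match(text, "dense \\(density\\)")
  cfg <- render_config()
  hist_rects <- svg_rects(svg)
  hist_rects <- hist_rects[hist_rects$fill == cfg$hist_fill, ]
  expect_gt(nrow(hist_rects), 10L)
})

test_that("render rejects bad inputs with named tracks", {
  feats <- empty_features()
  expect_error(render(list(track_config("a", "gene", feats),
                           track_config("a", "gene", feats)),
                      gm_region("c", 1, 10)), "duplicate")
  expect_error(render(list(track_config("bad", "gene", 42)),
                      gm_region("c", 1, 10)), "bad", class = "gm_render_error")
  expect_error(render(list(track_config("a", "gene", feats)),
                      gm_region("c", 1, 10), pixel_width = 0),
               class = "gm_argument_error")
  expect_error(track_config("x", "sidebar", feats), class = "gm_argument_error")
  expect_error(track_config("x", "gene", feats, height_px = -5),
               class = "gm_argument_error")
})

test_that("ideograms scale band widths proportionally", {
  bands <- data.frame(
    chrom = "chrI", start = c(1L, 500001L), end = c(500000L, 1000000L),
    name = c("p1", "q1"), stain = c("gneg", "gpos100"))
  frag <- render_ideogram(bands, "chrI", width = 500, height = 20)
  rects <- svg_rects(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg">',
    paste(frag, collapse = ""), "</svg>"))
  expect_identical(nrow(rects), 2L)
  expect_true(all(abs(rects$w - 250) < 0.5))
  # full-chromosome highlight spans the whole width
  frag2 <- render_ideogram(bands, "chrI", highlight = gm_region("chrI", 1, 1000000L),
                           width = 500, height = 20)
  rects2 <- svg_rects(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg">',
    paste(frag2, collapse = ""), "</svg>"))
  hl <- rects2[nrow(rects2), ]
  expect_lt(abs(hl$x), 1e-9)
  expect_lt(abs(hl$w - 500), 1e-9)
  expect_error(render_ideogram(bands, "chrMissing"), class = "gm_argument_error")
})

test_that("random band tables keep widths proportional within half a pixel", {
  set.seed(703)
  for (rep in 1:10) {
    n <- sample(3:10, 1L)
    edges <- sort(sample.int(2e6, n + 1L))
    stains <- sample(c("gneg", "gpos25", "gpos50", "gpos75", "gpos100"),
                     n, replace = TRUE)
    bands <- data.frame(chrom = "chrR", start = head(edges, n) + 1L,
                        end = edges[-1L], name = paste0("b", 1:n),
                        stain = stains)
    width <- 600
    frag <- render_ideogram(bands, "chrR", width = width, height = 15)
    rects <- svg_rects(paste0(
      '<svg xmlns="http://www.w3.org/2000/svg">',
      paste(frag, collapse = ""), "</svg>"))
    sc <- width / max(bands$end)
    expect_identical(nrow(rects), n)
    expect_true(all(abs(rects$w - (bands$end - bands$start + 1L) * sc) <= 0.5))
  }
})
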