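#' Render a multi-track genome view to a standalone SVG document
#'
#' Lays out, top to bottom: a coordinate ruler, the given tracks in list
#' order (each at the level of detail picked by [choose_lod()]), legends for
#' the gene-biotype and variant-consequence palettes, and a status line with
#' the region string and the scale. Gene tracks draw transcripts as exon
#' boxes joined by an intron line with strand arrows; coverage tracks draw
#' per-pixel depth bars with mismatching bases over-plotted in the base
#' palette at base-level zoom. Rendering is a pure function of its inputs:
#' repeated calls are byte-identical.
#'
#' @param tracks List of [track_config()] objects (unique ids).
#' @param region A [gm_region()].
#' @param pixel_width Canvas width in pixels (> 0).
#' @param config A [render_config()].
#' @return The SVG document as one string.
#' @export
render <- function(tracks, region, pixel_width = 1200L,
                   config = render_config()) {
  if (!is.numeric(pixel_width) || pixel_width < 1)
    stop_gm("argument", "pixel_width must be a positive number")
  if (inherits(tracks, "gm_track")) tracks <- list(tracks)
  ids <- vapply(tracks, function(t) t$track_id, "")
  if (anyDuplicated(ids))
    stop_gm("argument", "duplicate track_id '%s'", ids[duplicated(ids)][1L])
  pixel_width <- as.numeric(pixel_width)
  bpp <- region_length(region) / pixel_width

  blocks <- list(ruler_block(region, pixel_width, bpp, config))
  for (tr in tracks) {
    body <- tryCatch(
      switch(tr$kind,
        sequence = sequence_block(tr, region, pixel_width, bpp, config),
        gene = ,
        feature = ,
        variant = ,
        histogram = feature_block(tr, region, pixel_width, bpp, config),
        coverage = coverage_block(tr, region, pixel_width, bpp, config),
        ideogram = ideogram_block(tr, region, pixel_width, config)
      ),
      gm_error = function(e) stop_gm(
        "render", "track '%s': %s", tr$track_id, conditionMessage(e)),
      error = function(e) stop_gm(
        "render", "track '%s': %s", tr$track_id, conditionMessage(e))
    )
    blocks[[length(blocks) + 1L]] <- body
  }
  blocks[[length(blocks) + 1L]] <- legend_block(pixel_width, config)
  blocks[[length(blocks) + 1L]] <- status_block(region, bpp, pixel_width, config)

  y <- 0
  lines <- character(0)
  for (b in blocks) {
    lines <- c(lines, svg_group(y, b$body))
    y <- y + b$height + config$track_pad
  }
  total_h <- y
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(pixel_width), num(total_h), num(pixel_width), num(total_h)),
    svg_rect(0, 0, pixel_width, total_h, "#ffffff"),
    lines,
    "</svg>"
  )
  paste(doc, collapse = "\n")
}

x_of <- function(pos, region, bpp) (pos - region$start) / bpp

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

ruler_block <- function(region, width, bpp, config) {
  len <- region_length(region)
  step <- nice_step(len / 8)
  ticks <- seq(ceiling(region$start / step) * step, region$end, by = step)
  body <- c(svg_line(0, config$ruler_height - 1, width, config$ruler_height - 1,
                     "#333333"))
  for (t in ticks) {
    x <- clamp(x_of(t, region, bpp), 0, width)
    body <- c(body,
              svg_line(x, config$ruler_height - 6, x, config$ruler_height - 1, "#333333"),
              svg_text(x, config$ruler_height - 9,
                       formatC(t, format = "d", big.mark = ","),
                       config$font_px - 2, anchor = "middle"))
  }
  list(height = config$ruler_height, body = body)
}

nice_step <- function(raw) {
  mag <- 10^floor(log10(max(raw, 1)))
  for (m in c(1, 2, 5, 10)) if (m * mag >= raw) return(m * mag)
  10 * mag
}

track_title <- function(track, mode, config) {
  svg_text(2, config$font_px,
           paste0(track$track_id, if (mode == "histogram") " (density)" else ""),
           config$font_px, fill = "#555555")
}

sequence_block <- function(track, region, width, bpp, config) {
  mode <- choose_lod("sequence", bpp, config = config)
  y0 <- config$font_px + 4
  body <- track_title(track, mode, config)
  if (mode == "sequence") {
    bases <- strsplit(get_sequence(track$source, region), "")[[1L]]
    pal <- config$base_palette
    for (i in seq_along(bases)) {
      x <- x_of(region$start + i - 1 + 0.5, region, bpp)
      col <- if (bases[i] %in% names(pal)) pal[[bases[i]]] else pal[["default"]]
      body <- c(body, svg_text(x, y0 + config$font_px, bases[i],
                               config$font_px, fill = col, anchor = "middle"))
    }
  } else {
    body <- c(body, svg_text(2, y0 + config$font_px,
                             "sequence hidden at this zoom", config$font_px - 2,
                             fill = "#999999"))
  }
  list(height = y0 + config$font_px + 4, body = body)
}

# shared by gene / feature / variant / histogram kinds
feature_block <- function(track, region, width, bpp, config) {
  feats <- resolve_track_features(track, region)
  mode <- if (track$kind == "histogram") "histogram" else
    choose_lod(track$kind, bpp, nrow(feats), config)
  body <- track_title(track, mode, config)
  y0 <- config$font_px + 4
  if (mode == "histogram") {
    h <- track$height_px
    nbins <- max(1L, as.integer(width %/% config$hist_bin_px))
    d <- density_counts(feats, region, nbins)
    top <- max(d$counts, 1L)
    bw <- width / nbins
    for (i in seq_len(nbins)) {
      if (d$counts[i] == 0L) next
      bh <- d$counts[i] / top * h
      body <- c(body, svg_rect((i - 1) * bw, y0 + h - bh, bw, bh, config$hist_fill))
    }
    body <- c(body, svg_text(width - 2, y0 + config$font_px - 2,
                             sprintf("max %d", max(d$counts, 0L)),
                             config$font_px - 2, fill = "#999999", anchor = "end"))
    return(list(height = y0 + h + 2, body = body))
  }
  units <- glyph_units(feats, track, region, width, bpp, config)
  if (length(units$x0) == 0L)
    return(list(height = y0 + config$row_height, body = body))
  rows <- pack_rows(units$x0, units$x1, config$gap_px)
  gh <- config$glyph_height
  for (i in seq_along(rows)) {
    yy <- y0 + rows[i] * config$row_height
    body <- c(body, draw_unit(units$unit[[i]], units$x0[i], units$x1[i], yy,
                              gh, region, bpp, width, track, config))
  }
  list(height = y0 + (max(rows) + 1L) * config$row_height + 2, body = body)
}

# one drawable unit = a transcript with its exons, or a plain box
glyph_units <- function(feats, track, region, width, bpp, config) {
  pal <- merged_palette(track, config)
  units <- list()
  if (nrow(feats) > 0L) {
    tx <- feats[feats$ftype == "transcript", , drop = FALSE]
    exons <- feats[feats$ftype == "exon", , drop = FALSE]
    gene_ids <- feats$id[feats$ftype == "gene"]
    covered_genes <- unique(tx$parent)
    for (i in seq_len(nrow(tx))) {
      units[[length(units) + 1L]] <- list(
        type = "tx", start = tx$start[i], end = tx$end[i],
        strand = tx$strand[i],
        label = if (nzchar(tx$name[i])) tx$name[i] else tx$id[i],
        color = color_for(tx[i, ], pal),
        exons = exons[exons$parent == tx$id[i], , drop = FALSE]
      )
    }
    rest <- feats[!(feats$ftype == "transcript" |
                      (feats$ftype == "exon" & feats$parent %in% tx$id) |
                      (feats$ftype == "gene" & feats$id %in% covered_genes)), ,
                  drop = FALSE]
    for (i in seq_len(nrow(rest))) {
      units[[length(units) + 1L]] <- list(
        type = "box", start = rest$start[i], end = rest$end[i],
        strand = rest$strand[i],
        label = if (nzchar(rest$name[i])) rest$name[i] else rest$id[i],
        color = color_for(rest[i, ], pal), exons = NULL
      )
    }
  }
  if (length(units) == 0L)
    return(list(x0 = numeric(0), x1 = numeric(0), unit = list()))
  x0 <- vapply(units, function(u) clamp(x_of(u$start, region, bpp), 0, width), 0)
  x1 <- vapply(units, function(u)
    clamp(max(x_of(u$end + 1L, region, bpp),
              x_of(u$start, region, bpp) + 1), 0, width), 0)
  ord <- order(x0, x1, seq_along(units), method = "radix")
  list(x0 = x0[ord], x1 = x1[ord], unit = units[ord])
}

draw_unit <- function(u, x0, x1, y, gh, region, bpp, width, track, config) {
  body <- character(0)
  if (u$type == "tx") {
    mid <- y + gh / 2
    body <- c(body, svg_line(x0, mid, x1, mid, u$color))
    if (u$strand %in% c("+", "-") &&
        x1 >= x0 + config$arrow_spacing_px / 2) {
      ax <- seq(x0 + config$arrow_spacing_px / 2, x1,
                by = config$arrow_spacing_px)
      for (a in ax) {
        dx <- if (u$strand == "+") 3 else -3
        body <- c(body,
                  svg_line(a - dx, mid - 2.5, a + dx, mid, u$color),
                  svg_line(a + dx, mid, a - dx, mid + 2.5, u$color))
      }
    }
    ex <- u$exons
    for (j in seq_len(nrow(ex))) {
      ex0 <- clamp(x_of(ex$start[j], region, bpp), 0, width)
      ex1 <- clamp(x_of(ex$end[j] + 1L, region, bpp), 0, width)
      body <- c(body, svg_rect(ex0, y, max(ex1 - ex0, 0.5), gh, u$color))
    }
  } else {
    body <- c(body, svg_rect(x0, y, max(x1 - x0, 1), gh, u$color))
  }
  if (track$label_visible &&
      (x1 - x0) >= nchar(u$label) * config$char_px) {
    body <- c(body, svg_text(x0 + 1, y + gh - 1.5, u$label,
                             config$font_px - 2, fill = "#111111"))
  }
  body
}

coverage_block <- function(track, region, width, bpp, config) {
  src <- track$source
  if (!is.list(src) || is.null(src$bam))
    stop_gm("argument", "coverage source must be list(bam =, fasta =)")
  cov <- bam_coverage(src$bam, region, fasta = src$fasta)
  y0 <- config$font_px + 4
  h <- track$height_px
  body <- track_title(track, "coverage", config)
  top <- max(cov$depth, 1L)
  if (bpp <= config$mismatch_bp_per_px) {
    # base resolution: one bar per base, mismatches stacked in base colours
    pal <- config$base_palette
    for (i in seq_along(cov$depth)) {
      if (cov$depth[i] == 0L) next
      x <- x_of(region$start + i - 1, region, bpp)
      w <- max(1 / bpp, 0.5)
      bh <- cov$depth[i] / top * h
      body <- c(body, svg_rect(x, y0 + h - bh, w, bh, "#b0b0b0"))
      yy <- y0 + h
      for (b in rownames(cov$mismatch)) {
        c_b <- cov$mismatch[b, i]
        if (c_b == 0L) next
        mh <- c_b / top * h
        yy <- yy - mh
        body <- c(body, svg_rect(x, yy, w, mh, pal[[b]]))
      }
    }
  } else {
    # aggregate: max depth per pixel column
    px <- pmin(as.integer(width) - 1L,
               as.integer(floor((seq_along(cov$depth) - 1L) / bpp)))
    agg <- vapply(split(cov$depth, px), max, 0L)
    cols <- as.integer(names(agg))
    for (k in seq_along(agg)) {
      if (agg[k] == 0L) next
      bh <- agg[k] / top * h
      body <- c(body, svg_rect(cols[k], y0 + h - bh, 1, bh, "#9aa5b1"))
    }
  }
  body <- c(body, svg_text(width - 2, y0 + config$font_px - 2,
                           sprintf("max %dx", max(cov$depth, 0L)),
                           config$font_px - 2, fill = "#999999", anchor = "end"))
  list(height = y0 + h + 2, body = body)
}

ideogram_block <- function(track, region, width, config) {
  bands <- track$source
  frag <- render_ideogram(bands, region$chrom, highlight = region,
                          width = width, height = track$height_px - 16,
                          config = config)
  body <- c(track_title(track, "ideogram", config),
            svg_group(config$font_px + 4, frag))
  list(height = config$font_px + 4 + track$height_px - 16 + 4, body = body)
}

#' Draw a chromosome ideogram
#'
#' A horizontal schematic of one chromosome: cytogenetic bands shaded by
#' Giemsa stain, the centromere (`acen` bands) drawn as facing triangles,
#' and an optional highlighted region as a translucent box over its scaled
#' position. Band widths are proportional to band lengths.
#'
#' @param cytobands A [read_cytoband()] data.frame.
#' @param chrom Chromosome to draw (must have bands).
#' @param highlight Optional [gm_region()] on the same chromosome.
#' @param width,height Fragment size in pixels.
#' @param config A [render_config()] (stain palette).
#' @return A character vector of SVG fragment lines (a `<g>` element).
#' @export
render_ideogram <- function(cytobands, chrom, highlight = NULL,
                            width = 600, height = 20,
                            config = render_config()) {
  bands <- cytobands[cytobands$chrom == chrom, , drop = FALSE]
  if (nrow(bands) == 0L)
    stop_gm("argument", "no cytobands for chromosome '%s'", chrom)
  pal <- config$stain_palette
  chrom_len <- max(bands$end)
  sc <- width / chrom_len
  body <- "<g>"
  for (i in seq_len(nrow(bands))) {
    x0 <- (bands$start[i] - 1L) * sc
    x1 <- bands$end[i] * sc
    fill <- if (bands$stain[i] %in% names(pal)) pal[[bands$stain[i]]] else
      pal[["default"]]
    if (bands$stain[i] == "acen") {
      # facing triangles: point towards the neighbouring acen band
      nxt_acen <- i < nrow(bands) && bands$stain[i + 1L] == "acen"
      if (nxt_acen) {
        body <- c(body, svg_polygon(c(x0, x1, x0), c(0, height / 2, height), fill))
      } else {
        body <- c(body, svg_polygon(c(x1, x0, x1), c(0, height / 2, height), fill))
      }
    } else {
      body <- c(body, svg_rect(x0, 0, x1 - x0, height, fill, stroke = "#555555"))
    }
  }
  if (!is.null(highlight) && highlight$chrom == chrom) {
    hx0 <- (highlight$start - 1L) * sc
    hx1 <- min(highlight$end, chrom_len) * sc
    body <- c(body, svg_rect(hx0, -2, max(hx1 - hx0, 1), height + 4,
                             "#d62839", opacity = 0.35))
  }
  c(body, "</g>")
}

legend_block <- function(width, config) {
  body <- character(0)
  y <- 0
  for (set in list(list(title = "Genes", pal = config$biotype_palette),
                   list(title = "Variants", pal = config$consequence_palette))) {
    y <- y + config$font_px + 2
    x <- 2
    body <- c(body, svg_text(x, y, set$title, config$font_px, fill = "#333333"))
    x <- x + nchar(set$title) * config$char_px + 8
    labels <- setdiff(names(set$pal), "default")
    for (lab in labels) {
      body <- c(body, svg_rect(x, y - 8, 9, 9, set$pal[[lab]]),
                svg_text(x + 12, y, lab, config$font_px - 2, fill = "#333333"))
      x <- x + 12 + nchar(lab) * (config$char_px - 2) + 10
    }
    y <- y + 4
  }
  list(height = y, body = body)
}

status_block <- function(region, bpp, width, config) {
  txt <- sprintf("%s | %s bp | %s bp/px", format_region(region),
                 formatC(region_length(region), format = "d", big.mark = ","),
                 num(bpp))
  list(height = config$font_px + 4,
       body = svg_text(2, config$font_px, txt, config$font_px, fill = "#333333"))
}
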