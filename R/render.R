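TRACK_KINDS <- c("sequence", "gene", "feature", "variant", "coverage",
                 "histogram", "ideogram")

#' Rendering configuration
#'
#' All level-of-detail thresholds and geometry constants of the renderer,
#' overridable per call. Zoom is measured as `bp_per_px` (base pairs per
#' horizontal pixel). Defaults: sequence letters appear at 10 px per base or
#' more (`seq_bp_per_px = 0.1`); a feature track collapses to a density
#' histogram beyond 2,000 visible features (`max_glyphs`) or beyond 1,000
#' bp/px (`glyph_limit`); glyph rows are packed with a 2 px gap; text is
#' measured with a fixed 7 px/character estimate so layout never depends on
#' font metrics; coverage mismatches are over-plotted in the base palette at
#' base-level zoom (`mismatch_bp_per_px = 1`); intron strand arrows are
#' spaced every 50 px.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A named list.
#' @export
render_config <- function(...) {
  cfg <- list(
    seq_bp_per_px = 0.1,
    max_glyphs = 2000L,
    glyph_limit = 1000,
    gap_px = 2,
    char_px = 7,
    font_px = 11,
    row_height = 16,
    glyph_height = 10,
    hist_bin_px = 5,
    track_pad = 8,
    ruler_height = 26,
    mismatch_bp_per_px = 1,
    arrow_spacing_px = 50,
    hist_fill = "#7d9bbd",
    biotype_palette = biotype_palette(),
    consequence_palette = consequence_palette(),
    base_palette = base_palette(),
    stain_palette = stain_palette()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop_gm("argument", "unknown render option '%s'", bad[1L])
  cfg[names(over)] <- over
  cfg
}

#' Describe one track of a render
#'
#' @param track_id Unique label, also drawn as the track title.
#' @param kind One of `sequence`, `gene`, `feature`, `variant`, `coverage`,
#'   `histogram`, `ideogram`.
#' @param source What the track draws: a [gm_features()] data.frame, a
#'   [feature_store()], or a `function(region)` for feature-bearing kinds; a
#'   `DNAStringSet`/FASTA path for `sequence`; `list(bam =, fasta =)` for
#'   `coverage`; a [read_cytoband()] data.frame for `ideogram`.
#' @param height_px Track body height (positive; glyph tracks grow to fit
#'   their packed rows).
#' @param label_visible Draw feature labels (when they fit; labels clip,
#'   they never force extra rows).
#' @param palette Named colour overrides merged over the shipped palette for
#'   this track's colour key.
#' @return A `gm_track` list.
#' @export
track_config <- function(track_id, kind, source, height_px = NULL,
                         label_visible = TRUE, palette = NULL) {
  if (!kind %in% TRACK_KINDS)
    stop_gm("argument", "unknown track kind '%s'", kind)
  default_heights <- c(sequence = 24, gene = 80, feature = 56, variant = 36,
                       coverage = 80, histogram = 56, ideogram = 44)
  if (is.null(height_px)) height_px <- unname(default_heights[kind])
  if (!is.numeric(height_px) || height_px <= 0)
    stop_gm("argument", "height_px must be positive")
  structure(list(track_id = track_id, kind = kind, source = source,
                 height_px = height_px, label_visible = isTRUE(label_visible),
                 palette = palette),
            class = "gm_track")
}

#' Level-of-detail selection
#'
#' Decides how a track is drawn at the current zoom. Sequence tracks show
#' letters only at `bp_per_px <= seq_bp_per_px` (default: at least 10 px per
#' base), otherwise they are blank. Feature-bearing tracks show individual
#' glyphs only while both the feature count and the zoom allow it
#' (`feature_count <= max_glyphs` and `bp_per_px <= glyph_limit`); beyond
#' either threshold a density histogram is drawn instead. The choice is
#' monotone in `bp_per_px`: zooming out never switches a histogram back to
#' glyphs.
#'
#' @param kind Track kind (see [track_config()]).
#' @param bp_per_px Base pairs per pixel (> 0).
#' @param feature_count Number of features overlapping the window.
#' @param config A [render_config()].
#' @return `"sequence"`, `"blank"`, `"glyphs"` or `"histogram"` (other kinds
#'   return their own name).
#' @export
choose_lod <- function(kind, bp_per_px, feature_count = 0L,
                       config = render_config()) {
  if (bp_per_px <= 0) stop_gm("argument", "bp_per_px must be positive")
  if (kind == "sequence")
    return(if (bp_per_px <= config$seq_bp_per_px) "sequence" else "blank")
  if (kind == "histogram") return("histogram")
  if (kind %in% c("coverage", "ideogram")) return(kind)
  if (feature_count <= config$max_glyphs && bp_per_px <= config$glyph_limit)
    "glyphs" else "histogram"
}

#' Greedy first-fit row packing of glyph intervals
#'
#' Assigns each pixel interval to the lowest row where it fits with at least
#' `gap_px` clearance, processing glyphs sorted by (x0, x1, input order).
#' Intervals are treated as half-open `[x0, x1)`: touching glyphs may share
#' a row at gap 0. On sorted intervals first-fit is an optimal interval-graph
#' colouring, so with `gap_px = 0` the number of rows equals the maximum
#' overlap depth.
#'
#' @param x0,x1 Numeric vectors of pixel extents, `x1 >= x0`.
#' @param gap_px Minimum horizontal clearance between glyphs in a row.
#' @return Integer vector of 0-based row numbers, parallel to the input.
#' @export
pack_rows <- function(x0, x1, gap_px = 0) {
  stopifnot(length(x0) == length(x1))
  if (length(x0) == 0L) return(integer(0))
  if (any(x1 < x0)) stop_gm("argument", "x1 must be >= x0")
  ord <- order(x0, x1, seq_along(x0), method = "radix")
  rows <- integer(length(x0))
  row_end <- numeric(0)
  for (i in ord) {
    placed <- FALSE
    for (r in seq_along(row_end)) {
      if (x0[i] >= row_end[r] + gap_px) {
        rows[i] <- r - 1L
        row_end[r] <- x1[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      row_end <- c(row_end, x1[i])
      rows[i] <- length(row_end) - 1L
    }
  }
  rows
}

#' Colour for one feature
#'
#' Genes, transcripts and exons are keyed by biotype; variants by
#' consequence type; anything else (or an unknown/empty label) falls back to
#' the palette's `default` entry. Pure lookup: same feature, same colour.
#'
#' @param feature A single-row [gm_features()] data.frame (or list with
#'   `ftype` and the label fields).
#' @param palette Named colour vector with a `default` entry; defaults to
#'   the shipped palette matching the feature's kind.
#' @return A hex colour string.
#' @export
color_for <- function(feature, palette = NULL) {
  ftype <- feature$ftype[1L]
  label <- if (ftype == "variant") feature$consequence[1L] else feature$biotype[1L]
  if (is.null(palette))
    palette <- if (ftype == "variant") consequence_palette() else biotype_palette()
  if (!"default" %in% names(palette))
    stop_gm("argument", "palette must define a 'default' colour")
  if (!is.na(label) && nzchar(label) && label %in% names(palette))
    unname(palette[label]) else unname(palette["default"])
}

merged_palette <- function(track, config) {
  base <- if (track$kind == "variant") config$consequence_palette else
    config$biotype_palette
  if (!is.null(track$palette)) base[names(track$palette)] <- track$palette
  base
}

resolve_track_features <- function(track, region) {
  src <- track$source
  if (inherits(src, "gm_store")) return(query(src, region))
  if (is.function(src)) return(sort_features(filter_overlap(src(region), region)))
  if (inherits(src, "gm_features") || is.data.frame(src))
    return(sort_features(filter_overlap(src, region)))
  stop_gm("argument", "track '%s' has an unqueryable source", track$track_id)
}
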