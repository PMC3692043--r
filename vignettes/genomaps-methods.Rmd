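---
title: "genomaps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genomaps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomaps)
```

genomaps is a desk-scale re-creation of the computational core of a
browser-style genome viewer: everything such a viewer does between "the user
asked for chr7:100,000–120,000" and "here is the picture", minus the
interactive UI. This vignette records the model, the tunable parameters and
the design choices, in the order data flows through the package.

## Coordinate conventions and the feature model

All user-visible and JSON-exchanged coordinates are 1-based with both ends
inclusive, the convention of GFF and VCF. Internally, arithmetic that slices
sequences or assigns bins converts once to 0-based half-open pairs through
`to_internal()` / `to_display()` and converts back at the boundary. Keeping a
single conversion point is the whole design: every off-by-one class of bug is
confined to two ten-line functions that are property-tested as exact inverses.
BED input, which is 0-based half-open on disk, is shifted at read time
(`start = col2 + 1`).

Chromosome names are compared verbatim. The package never strips or adds
`chr` prefixes, because silent renaming corrupts joins between files that
disagree; a user who needs aliasing can rename at the source.

Every annotation becomes a row of one canonical table (`gm_features`):
id, name, chrom, start, end, strand, ftype (gene / transcript / exon /
variant / generic), biotype, consequence, parent, and an open `attrs`
key–value map. Gene-model hierarchy is carried by `parent` ids, variants
carry ref/alt in `attrs`, and the same table serializes to the versioned JSON
exchange document (`to_json()` / `from_json()`, schema `"1.0"`, fixed key
order, byte-stable). The schema is an original design for this toolkit; no
wire compatibility with any public service is claimed.

Records that carry no identifier of their own (plain BED lines, GFF rows
without `ID`) get content-derived ids (coordinates plus an occurrence
counter) rather than line numbers, so that a whole-file scan and a
byte-range indexed read of the same file produce identical features.

## Region-indexed reading of plain text formats

Browser-style access needs "the features overlapping this window" without
reading the whole file. For bgzip-compressed files the field uses tabix; for
the plain local files a user drags into a viewer, genomaps builds its own
chunk-offset table (`build_index()`): one pass over the sorted file assigns
each record to the fixed-width bin containing its start (default 50,000 bp)
and records, per (chromosome, bin), the contiguous byte range of records
starting there, plus the per-chromosome maximum record span. A query then
reads only the byte ranges of the bins covering the window, extended leftward
by enough bins to reach any record long enough to still overlap
(`ceil(max_span / chunk_size)` bins). This makes index completeness a
provable property rather than a heuristic, and the suite checks
`indexed_query == full scan + overlap filter` on hundreds of random regions,
including crafted bin-boundary records. Unsorted input is rejected at build
time with the first offending line, never silently tolerated.

BAM is deliberately different: it already ships a native index, so coverage
queries delegate to the `.bai` via Rsamtools and no bespoke index is built.
FASTA goes through Biostrings.

Two further reader conventions matter downstream. Features overlapping a
query are returned whole, never clipped to the window — a glyph that pokes
past the screen edge must keep its true extent or panning would make shapes
jump. And the variant consequence label is read from a single configurable
INFO key (default `CSQ_TYPE`) rather than from VEP/SnpEff annotation
dialects; parsing those is a project of its own and out of scope, and the
fixture generator writes the same key.

## Coverage and mismatch pileup

`bam_coverage()` computes per-base depth and per-base mismatch counts over a
region. Depth counts a read at a position only when a reference-aligned
CIGAR op (`M`, `=`, `X`) covers it: deletions (`D`) and splice gaps (`N`)
leave a gap and soft/hard clips never count, matching the pileup semantics
genome viewers display at base resolution. Mismatches are tallied per
alternate base against the reference. The implementation walks CIGARs
read-by-read; tests compare it against a naive per-read per-base oracle that
parses the SAM text directly, and against `Rsamtools::pileup` as an
independent second route.

## The chunked cache and pre-fetching

`feature_store()` wraps any region-queryable source in a cache of
fixed-width chunks. The store's contract is that it is a *pure latency
layer*: its answers are always identical to a direct source query, repeated
queries cost zero source fetches, and `prefetch()` (which warms the
adjacent window of equal width, the way a browser pre-renders the region
the user is panning toward) can change timing but never results. Tests
enforce each clause literally, with a fetch counter and paired
with/without-prefetch runs.

Chunk ownership is by feature start. Completeness under overlap queries is
guaranteed by two mechanisms: the query always also scans the bin
immediately left of the window (sufficient for any feature no longer than
one chunk), and features longer than a chunk are additionally recorded in a
per-store overflow list consulted on every query. Because long features are
both chunk-owned and overflow-listed, assembly deduplicates by feature id;
this is why stable ids are part of the model's contract. Eviction removes
the least recently fetched chunk beyond a capacity of 256 chunks; the
suite forces capacity 1 and re-checks oracle equality.

Defaults — 50,000 bp chunks, 256-chunk capacity, pre-fetch of one full
window width — are configuration, not claims: a few chunks cover a
screenful at gene-level zoom, and the numbers are documented so they can be
changed without re-deriving anything.

## Density histograms

When a window holds too many features to draw individually, the viewer
shows binned feature density. `density_histogram()` bins features by their
*start* position (`counts[i]` counts starts with
`floor((s - start) / bin_width) = i - 1`, last bin closed). Binning by
start rather than by overlap is a deliberate trade: a long feature is
counted once, not once per bin it touches, which makes the conservation
invariant exact — counts always sum to the number of feature starts inside
the region — at the price of attributing a feature entirely to its leftmost
bin. The invariant is asserted for every tested input, including on the
server side of the HTTP service.

## Rendering and level of detail

`render()` produces a standalone SVG 1.1 document: ruler, tracks in list
order, palette legends, status line. Determinism is treated as a
correctness property, not an aesthetic one — repeated renders must be
byte-identical, because the suite and any cache of rendered tiles rely on
it. That dictates several numerical choices: all coordinates are formatted
to exactly two decimals; text width is estimated with a fixed 7 px/character
constant instead of querying font metrics; labels are drawn only when they
fit inside their glyph and clip rather than force layout changes; no
timestamps or unordered iteration anywhere.

Level of detail (`choose_lod()`) is a function of `bp_per_px`, the zoom
measure. Sequence letters appear at 10 px per base or better
(`bp_per_px <= 0.1`). Feature tracks draw individual glyphs while the
window holds at most 2,000 features *and* `bp_per_px <= 1000`; beyond
either threshold they collapse to the density histogram. The original
viewer this emulates states none of these numbers, so they are configurable
with these documented defaults, and the suite instead checks the *shape* of
the rule: monotonicity (zooming out never un-collapses a histogram).

Row packing (`pack_rows()`) is greedy first-fit over glyphs sorted by
(x0, x1, input order), with intervals treated as half-open so touching
glyphs can share a row at gap 0. On sorted intervals first-fit colours an
interval graph optimally, so rows used equal the maximum overlap depth —
checked against a sweep-line oracle. The default inter-glyph gap is 2 px.

Transcripts draw as exon boxes joined by a mid-height intron line with
strand chevrons every 50 px (suppressed for strand `.`, which means
unstranded). Colours key off biotype for gene models and consequence type
for variants, with legends for both palettes at the bottom of every
document; the shipped hex palettes are this package's own choice (the
emulated viewer shows legends but prints no colour values, so no colour
matching is claimed). Coverage tracks draw per-pixel depth bars, switching
to per-base bars with mismatch counts over-plotted in the base palette once
`bp_per_px <= 1`. Ideograms shade cytobands by Giemsa stain, draw `acen`
pairs as facing triangles, and mark the current window as a translucent
box.

## The HTTP service

The service exports exactly what the library computes — the route handler
is a plain function (`handle_request()`) over a registry of indexed files,
and `start_service()` is a thin httpuv loop around it. This split is what
makes the service testable: the suite checks byte equality of endpoint
bodies against in-process calls over random regions, and only one
end-to-end test exercises a live socket. Responses are gzip-compressed
when the client advertises acceptance; the service holds no per-client
state, so request order can never change a body.

## The fixture generator

`simulate_dataset()` exists so the whole toolkit is testable offline: it
writes a uniform-random genome, non-overlapping gene loci with nested
transcript/exon records, annotated variants whose REF alleles match the
genome, uniformly placed all-`M` reads whose bases match the genome except
for simulated errors, and a cytoband partition — mutually consistent by
construction and byte-reproducible under the seed (`validate_dataset()`
re-checks the cross-file guarantees, and determinism is asserted at the
md5 level including the BAM).

The defaults are the package's study conditions: one 100 kb chromosome, 20
genes of 0.5–2.5 kb (about 30% occupancy, placed by rejection sampling
with a 10× attempt cap that fails loudly rather than under-delivering),
1–3 transcripts per gene with 2–6 exons, 200 variants (90% SNVs, 10% short
deletions), 100 bp reads at 10× mean coverage with a 1% per-base error
rate. Read count is the closed form `round(coverage × length /
read_length)`. Randomness comes from R's seeded generator, scoped so the
caller's RNG state is restored afterwards.

These fixtures exercise the machinery; they do not model biology. Uniform
base composition, uniform read placement, all-`M` alignments and
independent errors mean that passing tests demonstrate the correctness of
indexing, caching, pileup arithmetic and rendering — not robustness to
spliced alignments, indel-bearing reads, extreme GC, overlapping gene
dialects or malformed real-world files beyond the malformations the
readers explicitly handle.

## Problem sizes and verification

The default verification workload — the scale the package's own claims are
made at — is: 100 random regions per text format for the oracle-equality
checks, the full 100 kb chromosome for pileup-vs-naive comparison, 1,000
cases per round-trip property, and a four-track 10 kb render at 1,200 px,
repeated both directly and through a live HTTP server. `scripts/acceptance.R`
re-runs that workload from scratch under a caller-supplied seed and writes
the measured quantities as JSON.

## Known limitations

BigWig/BigBed, CRAM, GTF and bgzip/tabix inputs are out of scope, as are
assembly liftover, multi-assembly coordinates, VEP/SnpEff consequence
strings, font-accurate typography and any interactive behaviour. The cache
is in-process and per-session only. PNG export, where wanted, should
rasterize the SVG externally; only the SVG bytes carry the determinism
guarantee.
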