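Package: genomaps
Title: Desk-Scale Genome Browser Core: Region Queries, Track Rendering and a JSON Feature Service
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-addressable ingestion of standard genomic formats (FASTA,
    GFF3, BED, VCF, BAM, UCSC cytoband tables) into a canonical JSON feature
    model; a chunk-aligned cache with pre-fetching, feature-density histograms
    and gene-name prefix search; deterministic zoom-dependent SVG track
    rendering (sequence, packed glyphs, density histograms, ideograms, BAM
    coverage with per-base mismatches); a small HTTP region-query service
    speaking the same JSON; and a seeded synthetic-fixture generator so the
    whole toolkit is testable offline against brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    httpuv,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    callr,
    curl,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    xml2
Config/testthat/edition: 3
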