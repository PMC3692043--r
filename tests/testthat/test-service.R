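service_fixture <- function() {
  paths <- sim_fixture()
  data_dir_registry(dirname(paths$gff), dataset = "sim")
}

test_that("region endpoints return exactly the indexed query result", {
  reg <- service_fixture()
  paths <- sim_fixture()
  idx <- list(gene = build_index(paths$gff, "gff"),
              variant = build_index(paths$vcf, "vcf"),
              generic = build_index(paths$bed, "bed"))
  set.seed(801)
  for (i in 1:15) {
    r <- rand_region()
    for (res in names(idx)) {
      resp <- handle_request(reg, sprintf("/api/sim/region/%s/%s",
                                          format_region(r), res))
      expect_identical(resp$status, 200L)
      fmt <- c(gene = "gff", variant = "vcf", generic = "bed")[[res]]
      expect_identical(resp$body, to_json(indexed_query(idx[[res]], r), fmt))
    }
  }
})

test_that("sequence and cytoband resources serve their slices", {
  reg <- service_fixture()
  paths <- sim_fixture()
  resp <- handle_request(reg, "/api/sim/region/chrS1:101-110/sequence")
  expect_identical(resp$status, 200L)
  parsed <- jsonlite::fromJSON(resp$body)
  expect_identical(parsed$sequence,
                   get_sequence(paths$fasta, gm_region("chrS1", 101, 110)))
  bands <- handle_request(reg, "/api/sim/region/chrS1:1-100000/cytoband")
  feats <- from_json(bands$body)
  expect_identical(nrow(feats), nrow(read_cytoband(paths$cytoband)))
  expect_true(all(vapply(feats$attrs, function(a) "stain" %in% names(a), TRUE)))
})

test_that("histogram endpoint equals the library density call", {
  reg <- service_fixture()
  paths <- sim_fixture()
  st <- feature_store(file_source(paths$vcf, "vcf"))
  r <- gm_region("chrS1", 1L, 100000L)
  resp <- handle_request(reg, "/api/sim/region/chrS1:1-100000/histogram",
                         list(bins = "5", source = "variant"))
  parsed <- jsonlite::fromJSON(resp$body)
  d <- density_histogram(st, r, 5L)
  expect_identical(as.integer(parsed$counts), d$counts)
  expect_identical(sum(parsed$counts), sum(d$counts)) # conservation held server-side
  set.seed(802)
  for (i in 1:10) {
    rr <- rand_region()
    resp <- handle_request(reg, sprintf("/api/sim/region/%s/histogram",
                                        format_region(rr)),
                           list(bins = "12", source = "gene"))
    gene_store <- feature_store(file_source(paths$gff, "gff"))
    expect_identical(
      as.integer(jsonlite::fromJSON(resp$body)$counts),
      density_histogram(gene_store, rr, 12L)$counts)
  }
})

test_that("search endpoint equals the in-process prefix search", {
  reg <- service_fixture()
  paths <- sim_fixture()
  st <- feature_store(file_source(paths$gff, "gff"), build_name_index = TRUE)
  some_name <- st$name_index$name[1L]
  for (prefix in c(substr(some_name, 1, 2), tolower(substr(some_name, 1, 3)), "Q")) {
    resp <- handle_request(reg, "/api/sim/search",
                           list(prefix = prefix, limit = "7"))
    got <- jsonlite::fromJSON(resp$body, simplifyVector = FALSE)
    want <- name_prefix_search(st, prefix, 7L)
    expect_identical(vapply(got, `[[`, "", "name"), want$name)
    if (nrow(want) > 0L) {
      expect_identical(
        vapply(got, `[[`, "", "region"),
        sprintf("%s:%d-%d", want$chrom, want$start, want$end))
    }
  }
})

test_that("unknown routes give JSON 404s and bad parameters give 400s", {
  reg <- service_fixture()
  expect_identical(handle_request(reg, "/api/sim/region/chrS1:1-10/foo")$status, 404L)
  expect_identical(handle_request(reg, "/api/nope/region/chrS1:1-10/gene")$status, 404L)
  expect_identical(handle_request(reg, "/api/sim/region/chrS1:10-1/gene")$status, 400L)
  expect_identical(handle_request(reg, "/api/sim/region/banana/gene")$status, 400L)
  expect_identical(handle_request(reg, "/api/sim/region/chrS1:1-10/histogram",
                                  list(bins = "0"))$status, 400L)
  expect_identical(handle_request(reg, "/api/sim/search",
                                  list(prefix = ""))$status, 400L)
  err <- jsonlite::fromJSON(handle_request(reg, "/api/sim/region/chrS1:1-10/foo")$body)
  expect_match(err$error, "foo")
})

test_that("identical requests yield identical bodies regardless of order", {
  reg <- service_fixture()
  a <- handle_request(reg, "/api/sim/region/chrS1:5000-25000/gene")
  handle_request(reg, "/api/sim/region/chrS1:1-99/variant")
  handle_request(reg, "/api/sim/search", list(prefix = "A"))
  b <- handle_request(reg, "/api/sim/region/chrS1:5000-25000/gene")
  expect_identical(a, b)
})

test_that("gzip encoding is applied on request and decompresses to equality", {
  reg <- service_fixture()
  resp <- handle_request(reg, "/api/sim/region/chrS1:1-50000/gene")
  plain <- genomaps:::encode_response(resp, "")
  gz <- genomaps:::encode_response(resp, "gzip, deflate")
  expect_null(plain$headers[["Content-Encoding"]])
  expect_identical(gz$headers[["Content-Encoding"]], "gzip")
  expect_lt(length(gz$body), length(plain$body))
  expect_identical(memDecompress(gz$body, type = "gzip"), plain$body)
})

test_that("YAML registries resolve relative paths and reject missing files", {
  paths <- sim_fixture()
  dir <- dirname(paths$gff)
  yml <- file.path(dir, "registry.yaml")
  writeLines(c(
    "datasets:",
    "  demo:",
    "    gene: {path: genes.gff, format: gff}",
    "    sequence: {path: genome.fa}"
  ), yml)
  reg <- load_registry(yml)
  expect_identical(names(reg), "demo")
  resp <- handle_request(reg, "/api/demo/region/chrS1:1-5000/gene")
  expect_identical(resp$status, 200L)
  writeLines(c(
    "datasets:",
    "  demo:",
    "    gene: {path: does_not_exist.gff}"
  ), yml)
  expect_error(load_registry(yml), class = "gm_io_error")
})
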