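# a source wrapper that counts how often the backing source is consulted
counting_source <- function(features) {
  n <- new.env()
  n$calls <- 0L
  src <- function(region = NULL) {
    n$calls <- n$calls + 1L
    filter_overlap(features, region)
  }
  list(source = src, counter = n)
}

test_that("a cold query fetches one chunk per bin and repeats hit the cache", {
  set.seed(601)
  feats <- rand_features(200L, chroms = "chr1", max_pos = 30000L)
  st <- feature_store(memory_source(feats), chunk_size = 10000L)
  r <- gm_region("chr1", 5000, 25000) # bins 0,1,2
  query(st, r)
  expect_identical(st$fetches, 3L)
  query(st, r)
  expect_identical(st$fetches, 3L) # zero new source fetches
})

test_that("store answers equal direct source queries over random regions", {
  set.seed(602)
  feats <- rand_features(400L, chroms = c("chr1", "chr2"), max_pos = 50000L,
                         max_len = 2000L)
  st <- feature_store(memory_source(feats), chunk_size = 7000L)
  for (i in 1:100) {
    r <- rand_region(c("chr1", "chr2"), 50000L, 12000L)
    expect_identical(query(st, r), sort_features(filter_overlap(feats, r)))
  }
})

test_that("features reaching into the window from outside are never missed", {
  feats <- gm_features(
    id = c("short_left", "long_left", "inside"),
    chrom = "chr1",
    start = c(9500L, 2000L, 20500L),
    end = c(10400L, 21000L, 20900L) # long_left spans many chunks
  )
  st <- feature_store(memory_source(feats), chunk_size = 1000L)
  r <- gm_region("chr1", 10001L, 10200L)
  expect_identical(query(st, r)$id, c("long_left", "short_left"))
  r2 <- gm_region("chr1", 20000L, 20100L)
  expect_identical(query(st, r2)$id, "long_left")
})

test_that("prefetch makes the adjacent window fetch-free and changes nothing", {
  set.seed(603)
  feats <- rand_features(300L, chroms = "chr1", max_pos = 60000L)
  cs <- counting_source(feats)
  st <- feature_store(cs$source, chunk_size = 5000L,
                      chrom_lengths = c(chr1 = 60000L))
  expect_error(prefetch(st), class = "gm_state_error") # needs a query first
  r <- gm_region("chr1", 10001L, 20000L)
  res1 <- query(st, r)
  prefetch(st, "right")
  before <- cs$counter$calls
  nxt <- query(st, gm_region("chr1", 20001L, 30000L))
  expect_identical(cs$counter$calls, before) # fully cache-resident
  # paired-run equality: a store without prefetching gives identical answers
  plain <- feature_store(memory_source(feats), chunk_size = 5000L)
  expect_identical(nxt, query(plain, gm_region("chr1", 20001L, 30000L)))
  expect_identical(res1, query(plain, r))
  # prefetch at the chromosome end clips without error
  query(st, gm_region("chr1", 55001L, 60000L))
  expect_silent(prefetch(st, "right"))
  query(st, gm_region("chr1", 1L, 5000L))
  expect_silent(prefetch(st, "left"))
})

test_that("prefetch failures are swallowed, queries still raise", {
  flaky <- function(region = NULL) stop("backend down")
  st <- feature_store(flaky, chunk_size = 1000L)
  expect_error(query(st, gm_region("chr1", 1, 10)), "backend down")
  st2 <- feature_store(memory_source(rand_features(5L)), chunk_size = 1000L)
  query(st2, gm_region("chr1", 1, 1000)) # next window needs an unseen chunk
  st2$source <- flaky
  expect_warning(prefetch(st2, "right"), "prefetch failed")
})

test_that("forced eviction (capacity 1) preserves oracle equality", {
  set.seed(604)
  feats <- rand_features(300L, chroms = "chr1", max_pos = 40000L)
  st <- feature_store(memory_source(feats), chunk_size = 4000L, capacity = 1L)
  for (i in 1:40) {
    r <- rand_region("chr1", 40000L, 10000L)
    expect_identical(query(st, r), sort_features(filter_overlap(feats, r)))
  }
  expect_identical(length(ls(st$chunks)), 1L)
})

test_that("repeating a query sequence never increases total fetches", {
  set.seed(605)
  feats <- rand_features(200L, chroms = "chr1", max_pos = 50000L)
  st <- feature_store(memory_source(feats), chunk_size = 5000L)
  regions <- replicate(15, rand_region("chr1", 50000L, 8000L), simplify = FALSE)
  for (r in regions) query(st, r)
  first_pass <- st$fetches
  for (r in regions) query(st, r)
  expect_identical(st$fetches, first_pass)
})

test_that("density histograms bin by start and conserve counts", {
  # ten features at the deciles of a 1000 bp region, five bins
  feats <- gm_features(id = sprintf("d%d", 1:10), chrom = "chr1",
                       start = seq(1L, 901L, by = 100L),
                       end = seq(1L, 901L, by = 100L) + 10L)
  st <- feature_store(memory_source(feats), chunk_size = 500L)
  d <- density_histogram(st, gm_region("chr1", 1, 1000), 5L)
  expect_identical(d$counts, rep(2L, 5L))
  expect_identical(sum(d$counts), 10L)
  # empty region
  d0 <- density_histogram(st, gm_region("chr1", 5000, 6000), 4L)
  expect_identical(d0$counts, rep(0L, 4L))
  expect_error(density_histogram(st, gm_region("chr1", 1, 10), 0L),
               class = "gm_range_error")
})

test_that("histogram counts match a naive per-feature assignment loop", {
  set.seed(606)
  feats <- rand_features(500L, chroms = "chr1", max_pos = 20000L)
  st <- feature_store(memory_source(feats), chunk_size = 3000L)
  for (nbins in c(1L, 7L, 50L)) {
    r <- gm_region("chr1", 501L, 15500L)
    d <- density_histogram(st, r, nbins)
    naive <- integer(nbins)
    bw <- region_length(r) / nbins
    for (i in seq_len(nrow(feats))) {
      s <- feats$start[i]
      if (feats$chrom[i] != r$chrom || s < r$start || s > r$end) next
      k <- min(nbins - 1L, floor((s - r$start) / bw))
      naive[k + 1L] <- naive[k + 1L] + 1L
    }
    expect_identical(d$counts, naive)
    expect_identical(sum(d$counts),
                     sum(feats$start >= r$start & feats$start <= r$end))
  }
})

test_that("name prefix search folds case and orders lexicographically", {
  feats <- gm_features(id = c("a", "b", "c"), name = c("BRCA2", "BRAF", "TP53"),
                       chrom = "chr1", start = c(100L, 300L, 500L),
                       end = c(200L, 400L, 600L))
  st <- feature_store(memory_source(feats), build_name_index = TRUE)
  expect_identical(name_prefix_search(st, "BR")$name, c("BRAF", "BRCA2"))
  expect_identical(name_prefix_search(st, "brca")$name, "BRCA2")
  expect_identical(name_prefix_search(st, "BR", limit = 1L)$name, "BRAF")
  expect_identical(nrow(name_prefix_search(st, "ZZZ")), 0L)
  expect_error(name_prefix_search(st, ""), class = "gm_argument_error")
  no_index <- feature_store(memory_source(feats))
  expect_error(name_prefix_search(no_index, "BR"), class = "gm_state_error")
})

test_that("prefix search equals a linear scan on random name sets", {
  set.seed(607)
  for (rep in 1:10) {
    n <- sample(5:40, 1L)
    feats <- rand_features(n, chroms = "chr1")
    st <- feature_store(memory_source(feats), build_name_index = TRUE)
    prefix <- sample(c("name", "name1", "NAME2", "x"), 1L)
    got <- name_prefix_search(st, prefix, limit = 100L)
    named <- feats[nzchar(feats$name), , drop = FALSE]
    want <- named$name[startsWith(tolower(named$name), tolower(prefix))]
    expect_identical(got$name, sort(want, method = "radix"))
  }
})
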