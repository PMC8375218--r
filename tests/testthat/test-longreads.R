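block_row <- function(read_id = "r", read_length = 5000L, read_start = 1L,
                      read_end = 500L, ref_start = 1000L, ref_end = 1499L,
                      strand = "+", identity = 0.99, evalue = NA_real_) {
  data.frame(read_id = read_id, read_length = read_length,
             read_start = read_start, read_end = read_end, ref_name = "ref",
             ref_start = ref_start, ref_end = ref_end, strand = strand,
             identity = identity, evalue = evalue, mapped = TRUE,
             stringsAsFactors = FALSE)
}

test_that("retention filters apply the canonical thresholds exactly", {
  # read length: 900 nt dropped, 1100 nt kept (threshold 1000, exclusive)
  short <- block_row(read_id = "a", read_length = 900L)
  long <- block_row(read_id = "b", read_length = 1100L)
  expect_equal(nrow(chainReadBlocks(rbind(short, long))), 1L)
  expect_equal(chainReadBlocks(rbind(short, long))$read_id, "b")
  expect_equal(nrow(chainReadBlocks(block_row(read_length = 1000L))), 0L)

  # block length: 150 nt dropped, 250 nt kept (threshold 200, exclusive)
  b150 <- block_row(read_end = 150L, ref_end = 1149L)
  b250 <- block_row(read_end = 250L, ref_end = 1249L)
  expect_equal(nrow(chainReadBlocks(b150)), 0L)
  expect_equal(nrow(chainReadBlocks(b250)), 1L)
  expect_equal(nrow(chainReadBlocks(block_row(read_end = 200L,
                                              ref_end = 1199L))), 0L)

  # identity: 0.85 dropped, 0.95 kept (threshold 0.90, exclusive)
  expect_equal(nrow(chainReadBlocks(block_row(identity = 0.85))), 0L)
  expect_equal(nrow(chainReadBlocks(block_row(identity = 0.95))), 1L)
  expect_equal(nrow(chainReadBlocks(block_row(identity = 0.90))), 0L)

  # e-value gate applies only when present
  expect_equal(nrow(chainReadBlocks(block_row(evalue = 1e-10))), 0L)
  expect_equal(nrow(chainReadBlocks(block_row(evalue = 1e-30))), 1L)
  expect_equal(nrow(chainReadBlocks(block_row(evalue = NA_real_))), 1L)
})

test_that("single collinear chains pass through and emit no events", {
  one <- block_row()
  chain <- chainReadBlocks(one)
  expect_equal(nrow(chain), 1L)
  expect_equal(nrow(detectRearrangements(chain)), 0L)

  # two collinear blocks, reference gap matching the read gap
  two <- rbind(block_row(read_start = 1L, read_end = 500L,
                         ref_start = 1000L, ref_end = 1499L),
               block_row(read_start = 531L, read_end = 1030L,
                         ref_start = 1530L, ref_end = 2029L))
  expect_equal(nrow(detectRearrangements(chainReadBlocks(two))), 0L)
})

test_that("an inverted middle block yields events at both locus edges", {
  chain <- rbind(
    block_row(read_start = 1L, read_end = 1000L,
              ref_start = 2001L, ref_end = 3000L, strand = "+"),
    block_row(read_start = 1001L, read_end = 1300L,
              ref_start = 3001L, ref_end = 3300L, strand = "-"),
    block_row(read_start = 1301L, read_end = 2300L,
              ref_start = 3301L, ref_end = 4300L, strand = "+"))
  ev <- detectRearrangements(chainReadBlocks(chain))
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$kind == "inverted"))
  expect_setequal(ev$ref_pos, c(3001L, 3300L))
})

test_that("reference shifts respect the 200 nt displacement threshold", {
  mk <- function(shift) rbind(
    block_row(read_start = 1L, read_end = 500L,
              ref_start = 1000L, ref_end = 1499L),
    block_row(read_start = 501L, read_end = 1000L,
              ref_start = 1500L + shift, ref_end = 1999L + shift))
  expect_equal(nrow(detectRearrangements(chainReadBlocks(mk(150L)))), 0L)
  expect_equal(nrow(detectRearrangements(chainReadBlocks(mk(200L)))), 0L)
  ev <- detectRearrangements(chainReadBlocks(mk(250L)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "displaced")
  expect_equal(ev$shift, 250L)
  expect_equal(ev$ref_pos, 1750L)
})

test_that("histogram bins conserve events and flag constructed hotspots", {
  ev0 <- detectRearrangements(chainReadBlocks(block_row()))
  h0 <- hotspotHistogram(ev0, 10000L)
  expect_true(all(h0$event_count == 0L))
  expect_false(any(h0$is_hotspot))

  set.seed(81)
  ev <- data.frame(ref_pos = sample(5200:5400, 30L, replace = TRUE))
  h <- hotspotHistogram(ev, 10000L, bin_width = 1000L)
  expect_equal(h$event_count[h$bin_index == 5L], 30L)
  expect_true(h$is_hotspot[h$bin_index == 5L])
  expect_equal(sum(h$event_count), 30L)

  # conservation on arbitrary positions
  ev2 <- data.frame(ref_pos = sample(1:9999, 500L, replace = TRUE))
  h2 <- hotspotHistogram(ev2, 10000L)
  expect_equal(sum(h2$event_count), 500L)
})

test_that("tightening filters never increases chains or events", {
  g <- makeGenome(50000, 2, seed = 82)
  pop <- assignOrientations(g$loci, c(0.5, 0.5), 100, seed = 83)
  lr <- simulateLongReads(g$genome, g$loci, pop, 200, error_rate = 0.03,
                          seed = 84)
  blocks <- splitMap(lr$reads, g$genome)
  prev_chains <- Inf; prev_events <- Inf
  for (ident in c(0.85, 0.9, 0.95)) {
    ch <- chainReadBlocks(blocks, min_identity = ident)
    ev <- detectRearrangements(ch)
    expect_lte(length(unique(ch$read_id)), prev_chains)
    expect_lte(nrow(ev), prev_events)
    prev_chains <- length(unique(ch$read_id)); prev_events <- nrow(ev)
  }
  prev_chains <- Inf
  for (blen in c(100L, 200L, 400L)) {
    ch <- chainReadBlocks(blocks, min_block_len = blen)
    expect_lte(length(unique(ch$read_id)), prev_chains)
    prev_chains <- length(unique(ch$read_id))
  }
})

test_that("planted inversions are recovered as hotspots end to end", {
  g <- makeGenome(50000, 3, seed = 85)
  pop <- assignOrientations(g$loci, c(0.5, 0.5, 0.5), 200, seed = 86)
  lr <- simulateLongReads(g$genome, g$loci, pop, 400, error_rate = 0,
                          seed = 87)
  blocks <- splitMap(lr$reads, g$genome)
  ev <- detectRearrangements(chainReadBlocks(blocks))
  h <- hotspotHistogram(ev, 50000L)
  gr <- lociRanges(g$loci)
  hot <- h[h$is_hotspot, ]
  overlaps_locus <- function(s, e)
    any(s <= GenomicRanges::end(gr) & e >= GenomicRanges::start(gr))
  # all hotspot bins overlap planted loci, every locus is hit
  expect_true(all(mapply(overlaps_locus, hot$ref_start, hot$ref_end)))
  for (j in seq_along(gr))
    expect_true(any(hot$ref_start <= GenomicRanges::end(gr)[j] &
                    hot$ref_end >= GenomicRanges::start(gr)[j]))
})
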