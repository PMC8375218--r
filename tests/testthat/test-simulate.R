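test_that("makeGenome plants literal inverted-repeat cassettes", {
  g <- makeGenome(30000, 5, seed = 21)
  loci <- g$loci
  expect_equal(length(loci), 5L)
  s <- as.character(g$genome[[1L]])
  la <- leftArm(loci); ra <- rightArm(loci)
  left_seq <- substring(s, GenomicRanges::start(la), GenomicRanges::end(la))
  right_seq <- substring(s, GenomicRanges::start(ra), GenomicRanges::end(ra))
  expect_true(all(left_seq == "GTTCGTTTAA"))
  expect_true(all(right_seq == rc_chr("GTTCGTTTAA")))
  expect_true(all(validateLoci(loci, g$genome)))
  sp <- spacerRegion(loci)
  expect_true(all(GenomicRanges::width(sp) %in% 183:186))
})

test_that("degenerate and deterministic genome generation", {
  g0 <- makeGenome(5000, 0, seed = 22, min_separation = 0L)
  expect_equal(length(g0$loci), 0L)
  expect_equal(nchar(as.character(g0$genome[[1L]])), 5000L)

  g1 <- makeGenome(20000, 3, seed = 23)
  g2 <- makeGenome(20000, 3, seed = 23)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(loci_df(g1$loci), loci_df(g2$loci))
  g3 <- makeGenome(20000, 3, seed = 24)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("orientation assignment respects boundaries and binomial sampling", {
  g <- makeGenome(20000, 3, seed = 25)
  pop <- assignOrientations(g$loci, c(1, 0, 0.3), 10000, seed = 26)
  expect_true(all(pop$assignment[, 1L]))
  expect_false(any(pop$assignment[, 2L]))
  # realised proportion within the exact binomial 99.9% envelope
  n_on <- sum(pop$assignment[, 3L])
  expect_gte(n_on, qbinom(0.0005, 10000, 0.3))
  expect_lte(n_on, qbinom(0.9995, 10000, 0.3))

  expect_error(assignOrientations(g$loci, c(0.5, 0.5), 100), "one on_fraction")
  expect_error(assignOrientations(g$loci, c(0.5, 0.5, 1.2), 100), "\\[0, 1\\]")
})

test_that("paired-read simulation matches its configured library design", {
  g <- makeGenome(20000, 2, seed = 27)
  pop <- assignOrientations(g$loci, c(0.5, 0.5), 1000, seed = 28)
  pr <- simulatePairedReads(g$genome, g$loci, pop, 10000, seed = 29)
  expect_true(all(Biostrings::width(pr$mate1) == 150L))
  expect_true(all(Biostrings::width(pr$mate2) == 150L))
  # Kolmogorov-Smirnov check of realised inserts against the configured
  # Normal(350, 35); truncation below 150 carries negligible mass
  ks <- suppressWarnings(
    stats::ks.test(pr$truth$insert, "pnorm", 350, 35))
  expect_gt(ks$p.value, 0.001)

  empty <- simulatePairedReads(g$genome, g$loci, pop, 0)
  expect_length(empty$mate1, 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("paired-read truth labels agree with locus geometry", {
  g <- makeGenome(20000, 2, seed = 30)
  pop <- assignOrientations(g$loci, c(1, 0), 100, seed = 31)
  pr <- simulatePairedReads(g$genome, g$loci, pop, 5000, seed = 32)
  tr <- pr$truth
  sp <- spacerRegion(g$loci)
  # every pair labelled with a locus must have a mate overlapping its spacer
  lab <- !is.na(tr$locus)
  expect_true(all(tr$spacer_overlap[lab] > 0L))
  expect_true(all(tr$spacer_overlap[!lab] == 0L))
  # states follow the degenerate fractions
  expect_true(all(tr$state[tr$locus %in% "locus_1"] == "ON"))
  expect_true(all(tr$state[tr$locus %in% "locus_2"] == "OFF"))
  # mate1 equals the ON-reference sequence for ON fragments away from loci
  clean <- which(!lab)[1L]
  s <- as.character(g$genome[[1L]])
  expect_equal(as.character(pr$mate1[[clean]]),
               substr(s, tr$start[clean], tr$start[clean] + 149L),
               tolerance = NULL)
})

test_that("long-read lengths follow the fitted heavy-tailed distribution", {
  pars <- fitLongReadLengths(1882, 4697)
  # the fit reproduces the target quantiles in closed form
  expect_equal(exp(pars[["meanlog"]]), 1882)
  iqr <- qlnorm(0.75, pars[["meanlog"]], pars[["sdlog"]]) -
    qlnorm(0.25, pars[["meanlog"]], pars[["sdlog"]])
  expect_equal(iqr, 4697, tolerance = 1e-9)

  g <- makeGenome(200000, 2, seed = 33)
  pop <- assignOrientations(g$loci, c(0.5, 0.5), 500, seed = 34)
  lr <- simulateLongReads(g$genome, g$loci, pop, 10000, error_rate = 0,
                          seed = 35)
  med <- stats::median(lr$truth$length)
  expect_lt(abs(med - 1882) / 1882, 0.10)
  # KS against the truncated log-normal the generator is configured with
  lo <- plnorm(50, pars[["meanlog"]], pars[["sdlog"]])
  hi <- plnorm(200000, pars[["meanlog"]], pars[["sdlog"]])
  ptrunc <- function(q) (plnorm(q, pars[["meanlog"]], pars[["sdlog"]]) - lo) /
    (hi - lo)
  ks <- suppressWarnings(stats::ks.test(lr$truth$length, ptrunc))
  expect_gt(ks$p.value, 0.001)
})

test_that("long-read truth marks loci inverted relative to the reference", {
  g <- makeGenome(50000, 3, seed = 36)
  pop <- assignOrientations(g$loci, c(0, 1, 0.5), 50, seed = 37)
  lr <- simulateLongReads(g$genome, g$loci, pop, 300, error_rate = 0, seed = 38)
  tr <- lr$truth
  gr <- lociRanges(g$loci)
  ov1 <- tr$start <= GenomicRanges::end(gr)[1L] &
    tr$end >= GenomicRanges::start(gr)[1L]
  expect_true(all(grepl("locus_1", tr$flipped_loci[ov1])))
  expect_false(any(grepl("locus_2", tr$flipped_loci)))
})

test_that("metagenome mixtures hit the configured source ratio", {
  host <- makeGenome(30000, 0, seed = 39, min_separation = 0L)$genome
  phage <- makeGenome(30000, 0, seed = 40, min_separation = 0L)$genome
  mg0 <- simulateMetagenome(host, phage, 0, 5000, seed = 41)
  expect_equal(sum(mg0$truth$source == "phage"), 0L)

  mg1 <- simulateMetagenome(host, phage, 1, 20000, seed = 42)
  n_phage <- sum(mg1$truth$source == "phage")
  expect_gte(n_phage, qbinom(0.0005, 20000, 0.5))
  expect_lte(n_phage, qbinom(0.9995, 20000, 0.5))

  expect_error(simulateMetagenome(host, phage, -1, 100), ">= 0")
})

test_that("all generators are seed-deterministic", {
  g <- makeGenome(20000, 2, seed = 43)
  pop <- assignOrientations(g$loci, c(0.4, 0.6), 200, seed = 44)
  a <- simulatePairedReads(g$genome, g$loci, pop, 500, seed = 45)
  b <- simulatePairedReads(g$genome, g$loci, pop, 500, seed = 45)
  expect_identical(as.character(a$mate1), as.character(b$mate1))
  expect_identical(a$truth, b$truth)
  la <- simulateLongReads(g$genome, g$loci, pop, 100, seed = 46)
  lb <- simulateLongReads(g$genome, g$loci, pop, 100, seed = 46)
  expect_identical(as.character(la$reads), as.character(lb$reads))
  ma <- simulateMetagenome(g$genome, g$genome, 2, 100, seed = 47)
  mb <- simulateMetagenome(g$genome, g$genome, 2, 100, seed = 47)
  expect_identical(as.character(ma$reads), as.character(mb$reads))
})
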