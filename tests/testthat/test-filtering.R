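test_that("peak filter boundaries are inclusive and match brute force", {
  pk <- makePeaks("chr1", c(0, 100, 200), c(50, 150, 250),
                  enrichment = c(1.0, 0.9, 3), negLog10Q = c(2.0, 5, 1.99))
  kept <- filterPeaks(pk)
  # enrichment = 1 and -log10 q = 2 exactly is retained; the others fail
  expect_equal(kept$name, "p1")
  expect_error(filterPeaks(pk, minEnrichment = -1), "non-negative")

  set.seed(42)
  big <- makePeaks("chr1", seq(0, 9900, by = 100), seq(50, 9950, by = 100),
                   enrichment = round(stats::runif(100, 0, 3), 3),
                   negLog10Q = round(stats::runif(100, 0, 5), 3))
  kept <- filterPeaks(big, 1, 2)
  oracle <- which(vapply(seq_along(big), function(i)
    big$enrichment[i] >= 1 && big$negLog10Q[i] >= 2, logical(1)))
  expect_equal(which(big$name %in% kept$name), oracle)
})

test_that("call filter boundaries, absent fractions and brute force agree", {
  boundary <- modCalls("chr1", 1:3, "+", 5,
                       coverage = c(50L, 49L, 50L),
                       score = c(30, 30, 29.9),
                       fraction = c(0.7, 0.7, 0.7))
  expect_equal(GenomicRanges::start(filterCalls(boundary)), 1L)

  noFrac <- modCalls("chr1", 1L, "+", 5, 100L, 40, NA_real_)
  expect_length(filterCalls(noFrac, minFraction = 0.7), 0L)
  expect_length(filterCalls(noFrac, minScore = 0, minFraction = NULL), 1L)
  expect_error(filterCalls(noFrac, minFraction = 1.2), "0, 1")

  calls <- randomCalls(200, seed = 7)
  kept <- filterCalls(calls, 50, 30, 0.7)
  oracle <- vapply(seq_along(calls), function(i) {
    calls$coverage[i] >= 50 && calls$score[i] >= 30 &&
      !is.na(calls$fraction[i]) && calls$fraction[i] >= 0.7
  }, logical(1))
  expect_equal(GenomicRanges::start(kept), GenomicRanges::start(calls[oracle]))
})

test_that("per-chromosome mean-coverage mode drops whole chromosomes", {
  calls <- modCalls(rep(c("chrA", "chrB"), each = 2), c(1L, 2L, 1L, 2L), "+",
                    5, coverage = c(100L, 80L, 30L, 40L), score = 40,
                    fraction = 0.9)
  kept <- filterCalls(calls, minCoverage = 50, minScore = 0,
                      minFraction = NULL, perChromosomeCoverage = TRUE)
  expect_equal(unique(as.character(GenomicRanges::seqnames(kept))), "chrA")
  expect_equal(length(kept), 2L)  # chrA's cov-80 call survives via the mean
})

test_that("call-in-peak membership uses half-open peak boundaries", {
  pk <- makePeaks("chr1", 100, 150)
  atFirstBase <- modCalls("chr1", 101L, "+", 5, 100L, 40, 0.9)
  atBedStart <- modCalls("chr1", 100L, "+", 5, 100L, 40, 0.9)
  atBedEnd <- modCalls("chr1", 150L, "+", 5, 100L, 40, 0.9)
  pastEnd <- modCalls("chr1", 151L, "+", 5, 100L, 40, 0.9)
  expect_length(intersectCallsPeaks(atFirstBase, pk), 1L)
  expect_length(intersectCallsPeaks(atBedStart, pk), 0L)
  expect_length(intersectCallsPeaks(atBedEnd, pk), 1L)  # last covered base
  expect_length(intersectCallsPeaks(pastEnd, pk), 0L)
  expect_length(intersectCallsPeaks(atFirstBase, pk[0]), 0L)
})

test_that("intersection matches an all-pairs oracle and ignores peak order", {
  calls <- randomCalls(1000, seed = 11)
  set.seed(12)
  starts <- sample.int(9500, 50)
  pk <- makePeaks(sample(c("chr1", "chr2"), 50, replace = TRUE),
                  starts, starts + sample(50:400, 50, replace = TRUE))
  res <- intersectCallsPeaks(calls, pk)

  inPeak <- vapply(seq_along(calls), function(i) {
    p <- GenomicRanges::start(calls)[i]
    ch <- as.character(GenomicRanges::seqnames(calls))[i]
    any(as.character(GenomicRanges::seqnames(pk)) == ch &
          GenomicRanges::start(pk) <= p & p <= GenomicRanges::end(pk))
  }, logical(1))
  expect_equal(GenomicRanges::start(res), GenomicRanges::start(calls[inPeak]))

  shuffled <- intersectCallsPeaks(calls, pk[sample(length(pk))])
  expect_equal(GenomicRanges::start(shuffled), GenomicRanges::start(res))

  # a call inside two overlapping peaks appears exactly once
  twin <- intersectCallsPeaks(calls, c(pk, pk))
  expect_equal(length(twin), length(res))
})

test_that("conservative set recovers planted truth and records provenance", {
  inside <- modCalls("chr1", seq(110L, 145L, length.out = 10), "+",
                     5, 100L, 40, 0.9)
  outside <- modCalls("chr1", seq(500L, 900L, length.out = 10), "+",
                      5, 100L, 40, 0.9)
  pk <- makePeaks("chr1", c(100, 1000), c(150, 1100),
                  enrichment = c(5, 5), negLog10Q = c(10, 10))
  cs <- buildConservativeSet(c(inside, outside), pk)
  expect_equal(length(cs), 10L)
  expect_equal(GenomicRanges::start(conservativeCalls(cs)),
               GenomicRanges::start(inside))
  expect_equal(cutoffsUsed(cs)$minScore, 30)
  expect_equal(cutoffsUsed(cs)$minNegLog10Q, 2)

  # all peaks failing the enrichment cutoff empties the set
  weak <- makePeaks("chr1", 100, 150, enrichment = 0.5, negLog10Q = 10)
  expect_length(buildConservativeSet(c(inside, outside), weak), 0L)

  # degenerate cutoffs reduce to plain peak membership
  lax <- buildConservativeSet(c(inside, outside), pk, minCoverage = 0,
                              minScore = 0, minFraction = NULL,
                              minEnrichment = 0, minNegLog10Q = 0)
  expect_equal(length(lax), 10L)
})

test_that("duplicate calls are collapsed with a warning", {
  calls <- modCalls("chr1", c(5L, 5L, 6L), c("+", "+", "+"), 5, 100L, 40, 0.9)
  expect_warning(out <- collapseDuplicateCalls(calls), "duplicate")
  expect_equal(length(out), 2L)
  # same position on opposite strands is not a duplicate
  both <- modCalls("chr1", c(5L, 5L), c("+", "-"), 5, 100L, 40, 0.9)
  expect_silent(expect_length(collapseDuplicateCalls(both), 2L))
})

test_that("raising any cutoff never grows the filtered sets", {
  calls <- randomCalls(300, seed = 21)
  pk <- makePeaks("chr1", seq(0, 9000, by = 500), seq(300, 9300, by = 500),
                  enrichment = seq(0.2, 4, length.out = 19),
                  negLog10Q = seq(0, 9, length.out = 19))
  prevCalls <- length(calls) + 1L
  for (cov in c(0, 25, 50, 100)) {
    k <- filterCalls(calls, cov, 0, NULL)
    expect_lte(length(k), prevCalls)
    prevCalls <- length(k)
  }
  prevPeaks <- length(pk) + 1L
  for (q in c(0, 1, 2, 5)) {
    k <- filterPeaks(pk, 0, q)
    expect_lte(length(k), prevPeaks)
    prevPeaks <- length(k)
  }
})
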