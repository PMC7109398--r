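# smaller genomes than the regime defaults keep these structural checks fast;
# the full default regimes are exercised end-to-end in the acceptance tests

smallProk <- function(seed, nFalse = 400L, ...) {
  simulationConfig("prokaryote", seed = seed, genomeLength = 50000L,
                   nTrueOffMotif = 40L, nFalse = nFalse,
                   plantCopies = c(GATC = 25L, GANTC = 25L), ...)
}

test_that("background genomes honor GC content and are seed-deterministic", {
  cfg <- simulationConfig("prokaryote", seed = 5, genomeLength = 100000L)
  g <- generateGenome(cfg)
  af <- Biostrings::alphabetFrequency(g)[1, c("A", "C", "G", "T")]
  gc <- (af["C"] + af["G"]) / sum(af)
  expect_lt(abs(gc - 0.5), 0.02)

  g2 <- generateGenome(cfg)
  expect_identical(as.character(g[[1]]), as.character(g2[[1]]))

  allGC <- generateGenome(simulationConfig("prokaryote", seed = 5,
                                           genomeLength = 2000L,
                                           gcContent = 1))
  af2 <- Biostrings::alphabetFrequency(allGC)[1, ]
  expect_equal(unname(af2["A"] + af2["T"]), 0L)
  expect_error(simulationConfig("prokaryote", seed = 1, gcContent = 2),
               "0, 1")
  expect_error(simulationConfig("prokaryote", seed = 1, genomeLength = 10),
               "1 kb")
})

test_that("planted calls follow the configured truth design", {
  cfg <- smallProk(seed = 31)
  sim <- simulateDataset(cfg)
  truth <- sim$truth
  expect_equal(nrow(truth), length(sim$calls))
  # labels consistent: on-motif true calls carry a motif name
  expect_true(all(!is.na(truth$motifName[truth$onMotif])))
  expect_true(all(is.na(truth$motifName[!truth$onMotif])))
  # false calls only at non-motif adenines by construction
  expect_true(all(!truth$onMotif[!truth$isTrue]))

  # true IPD sample mean within 3 sd / sqrt(n) of the configured mean
  tIpd <- sim$calls$ipdRatio[truth$isTrue]
  expect_lt(abs(mean(tIpd) - cfg$trueIpdMean),
            3 * cfg$trueIpdSd / sqrt(length(tIpd)))
  fIpd <- sim$calls$ipdRatio[!truth$isTrue]
  expect_lt(abs(mean(fIpd) - cfg$falseIpdMean),
            3 * cfg$falseIpdSd / sqrt(length(fIpd)))
  expect_true(all(sim$calls$ipdRatio > 0))

  # zero false positives: every emitted call is true
  noFalse <- simulateDataset(smallProk(seed = 32, nFalse = 0L))
  expect_true(all(noFalse$truth$isTrue))
})

test_that("both regimes hit their motif-share conditions", {
  prok <- simulateDataset(simulationConfig("prokaryote", seed = 41))
  shareP <- mean(prok$truth$onMotif[prok$truth$isTrue])
  expect_gt(shareP, 0.93)   # prokaryote-like: ~95% of true calls on motifs
  expect_lt(shareP, 0.97)

  euk <- simulateDataset(simulationConfig("eukaryote", seed = 42))
  shareE <- mean(euk$truth$onMotif[euk$truth$isTrue])
  expect_lt(shareE, 0.03)   # eukaryote-like: under 3% on motifs
})

test_that("peaks cover true sites as configured and decoys stay off-target", {
  cfg <- smallProk(seed = 51, peakCoverageFraction = 1, decoyPeakCount = 0L)
  sim <- simulateDataset(cfg)
  truePos <- sim$truth$position[sim$truth$isTrue]
  inPeak <- vapply(truePos, function(p)
    any(GenomicRanges::start(sim$peaks) <= p &
          p <= GenomicRanges::end(sim$peaks)), logical(1))
  expect_true(all(inPeak))

  withDecoys <- simulateDataset(smallProk(seed = 52, decoyPeakCount = 10L))
  expect_gt(length(withDecoys$peaks), length(sim$peaks) / 2)
  expect_true(all(GenomicRanges::width(withDecoys$peaks) >= cfg$peakWidth))
})

test_that("emitted files are byte-stable and parse back to the same objects", {
  cfg <- smallProk(seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateDataset(cfg, d1)
  simulateDataset(cfg, d2)
  for (f in c("genome.fasta", "modifications.gff", "peaks.narrowPeak",
              "motifs.tsv", "truth.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  sim <- simulateDataset(cfg, d1)
  genome <- readGenome(file.path(d1, "genome.fasta"))
  expect_identical(as.character(genome[[1]]), as.character(sim$genome[[1]]))
  calls <- readModificationsGff(file.path(d1, "modifications.gff"))
  expect_equal(GenomicRanges::start(calls), GenomicRanges::start(sim$calls))
  expect_equal(calls$ipdRatio, sim$calls$ipdRatio)
  expect_equal(calls$fraction, sim$calls$fraction)
  peaks <- readNarrowPeak(file.path(d1, "peaks.narrowPeak"))
  expect_equal(GenomicRanges::start(peaks), GenomicRanges::start(sim$peaks))
  expect_equal(peaks$enrichment, sim$peaks$enrichment)
  motifs <- readMotifs(file.path(d1, "motifs.tsv"))
  expect_equal(motifPatterns(motifs), motifPatterns(cfg$motifs))
  truth <- readGroundTruth(file.path(d1, "truth.tsv"))
  expect_equal(truth$position, sim$truth$position)
  expect_equal(truth$isTrue, sim$truth$isTrue)
})
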