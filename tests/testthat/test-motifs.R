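test_that("palindromic and degenerate patterns match on both strands", {
  g <- Biostrings::DNAStringSet(c(chr1 = "GGATCC"))
  occ <- scanMotifs(g, MotifSet("dam", "GATC", 1L))
  # GATC is its own reverse complement: one occurrence per strand at 2..5
  expect_equal(length(occ), 2L)
  expect_equal(GenomicRanges::start(occ), c(2L, 2L))
  expect_equal(GenomicRanges::end(occ), c(5L, 5L))
  expect_setequal(as.character(GenomicRanges::strand(occ)), c("+", "-"))
  # methylated offset 1: the A at forward position 3; on the minus strand
  # the adenine pairs with the forward T at position 4
  plus <- occ[as.character(GenomicRanges::strand(occ)) == "+"]
  minus <- occ[as.character(GenomicRanges::strand(occ)) == "-"]
  expect_equal(unlist(plus$adeninePositions), 3L)
  expect_equal(unlist(minus$adeninePositions), 4L)

  # VATB (V = A/C/G, B = C/G/T) matches CATG
  vatb <- scanMotifs(Biostrings::DNAStringSet(c(c1 = "CATG")),
                     MotifSet("vatb", "VATB"))
  expect_true("+" %in% as.character(GenomicRanges::strand(vatb)))
  # CATG is also self-revcomp, so a minus occurrence exists too
  expect_equal(length(vatb), 2L)
})

test_that("overlapping occurrences are all reported and N never matches", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAAAA"))
  occ <- scanMotifs(g, MotifSet("a4", "AAAA"))
  plus <- occ[as.character(GenomicRanges::strand(occ)) == "+"]
  expect_equal(GenomicRanges::start(plus), c(1L, 2L))

  withN <- Biostrings::DNAStringSet(c(chr1 = "GANC"))
  expect_length(scanMotifs(withN, MotifSet("m", "GANC")), 0L)
  # motif longer than the chromosome: no occurrences, no error
  expect_length(scanMotifs(Biostrings::DNAStringSet(c(c1 = "ACG")),
                           MotifSet("m", "ACGTACGT")), 0L)
})

test_that("scanner agrees with a regex oracle across all IUPAC codes", {
  patterns <- c("GATC", "VATB", "RYSWKM", "BDHVN", "ANWT")
  for (i in 1:6) {
    s <- randomSeq(2000, seed = 100 + i, nN = if (i > 4) 20 else 0)
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "chrT"
    for (p in patterns) {
      occ <- scanMotifs(g, MotifSet("m", p))
      got <- data.frame(start = GenomicRanges::start(occ),
                        strand = as.character(GenomicRanges::strand(occ)))
      want <- oracleScan(p, s)
      if (is.null(want)) want <- data.frame(start = integer(0),
                                            strand = character(0))
      ord <- function(d) {
        d <- d[order(d$start, d$strand), , drop = FALSE]
        rownames(d) <- NULL
        d
      }
      expect_equal(ord(got), ord(want), info = paste(p, "seed", 100 + i))
    }
  }
})

test_that("minus-strand scanning mirrors plus-strand scanning of the revcomp", {
  s <- randomSeq(1500, seed = 222)
  g <- Biostrings::DNAStringSet(c(fwd = s))
  rc <- Biostrings::DNAStringSet(c(fwd = revcompStr(s)))
  for (p in c("GAWTC", "VATB")) {
    m <- MotifSet("m", p)
    occF <- scanMotifs(g, m)
    occR <- scanMotifs(rc, m)
    minusF <- occF[as.character(GenomicRanges::strand(occF)) == "-"]
    plusR <- occR[as.character(GenomicRanges::strand(occR)) == "+"]
    # mirror coordinates: start' = L - end + 1
    expect_equal(sort(1500 - GenomicRanges::end(minusF) + 1L),
                 sort(GenomicRanges::start(plusR)))
  }
})

test_that("call classification is strand-specific and matches an all-pairs oracle", {
  g <- Biostrings::DNAStringSet(c(chr1 = "GGATCC"))
  occ <- scanMotifs(g, MotifSet("dam", "GATC", 1L))
  onPlusA <- modCalls("chr1", 3L, "+", 5, 100L, 40, 0.9)
  onMinusSameCoord <- modCalls("chr1", 3L, "-", 5, 100L, 40, 0.9)
  expect_equal(as.list(classifyCalls(onPlusA, occ))[[1]], "dam")
  expect_length(as.list(classifyCalls(onMinusSameCoord, occ))[[1]], 0L)

  # random calls vs occurrences on a random sequence
  s <- randomSeq(3000, seed = 33)
  g2 <- Biostrings::DNAStringSet(c(chr1 = s))
  motifs <- MotifSet(c("dam", "vatb"), c("GATC", "VATB"), c(1L, NA))
  occ2 <- scanMotifs(g2, motifs)
  calls <- randomCalls(500, seed = 34, chroms = "chr1", maxPos = 3000L)
  labels <- classifyCalls(calls, occ2)
  # oracle: explicit loop over every (call, occurrence) pair
  ap <- occ2$adeninePositions
  for (i in seq_along(calls)) {
    pos <- GenomicRanges::start(calls)[i]
    str <- as.character(GenomicRanges::strand(calls))[i]
    hits <- character(0)
    for (j in seq_along(occ2)) {
      if (as.character(GenomicRanges::strand(occ2))[j] == str &&
          pos %in% ap[[j]])
        hits <- c(hits, occ2$motif[j])
    }
    expect_setequal(as.list(labels)[[i]], unique(hits))
  }
})

test_that("state proportions follow the printed ratio definitions", {
  lab <- function(...) IRanges::CharacterList(list(...))
  states <- list(
    "PacBio" = lab("dam", "dam", character(0), character(0)),
    "PacBio+threshold" = lab("dam", "dam", character(0))
  )
  rep <- computeStateProportions(states, motifNames = "dam")
  pm <- perMotifTable(rep)
  expect_equal(pm$proportion[pm$state == "PacBio"], 0.5)  # m=2, N=4
  expect_equal(pm$proportion[pm$state == "PacBio+threshold"], 2 / 3)
  tot <- totalsTable(rep)
  expect_equal(tot$M, c(2L, 2L))
  expect_equal(motifIncrease(rep), 2 / 3 - 1 / 2)

  allOn <- list(A = lab("m", "m"), B = lab("m"))
  repAll <- computeStateProportions(allOn, motifNames = "m")
  expect_true(all(totalsTable(repAll)$proportion == 1))

  # an empty state reports NA, never 0; an empty baseline errors
  withEmpty <- list(A = lab("m"), B = lab())
  expect_true(is.na(totalsTable(computeStateProportions(withEmpty))$proportion[2]))
  expect_error(computeStateProportions(list(A = lab(), B = lab("m"))),
               "empty")
})

test_that("proportions match brute-force counting on a random scenario", {
  set.seed(55)
  motifs <- c("m1", "m2")
  labels <- lapply(seq_len(500), function(i) {
    k <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
    sample(motifs, k)
  })
  keep <- stats::runif(500) < 0.4
  states <- list("PacBio" = IRanges::CharacterList(labels),
                 "PacBio+threshold" = IRanges::CharacterList(labels[keep]))
  rep <- computeStateProportions(states, motifNames = motifs)
  pm <- perMotifTable(rep)
  for (mo in motifs) {
    expect_equal(pm$m[pm$motif == mo & pm$state == "PacBio"],
                 sum(vapply(labels, function(l) mo %in% l, logical(1))))
  }
  M <- sum(lengths(labels) > 0)
  Mthr <- sum(lengths(labels[keep]) > 0)
  expect_equal(motifIncrease(rep), Mthr / sum(keep) - M / 500)
  # D * N equals the number of removed non-motif calls (algebraic identity)
  removedNonMotif <- sum(lengths(labels[!keep]) == 0)
  expect_equal(nonMotifDecrease(rep) * 500, removedNonMotif)
})

test_that("increase/decrease statistics follow their closed forms", {
  id <- increaseDecrease(N = 10, M = 6, Nthr = 5, Mthr = 4)
  expect_equal(id$I, 0.2)
  expect_equal(id$D, 0.3)
  # removing nothing changes nothing
  none <- increaseDecrease(N = 10, M = 6, Nthr = 10, Mthr = 6)
  expect_equal(none$I, 0)
  expect_equal(none$D, 0)
  # removing only non-motif calls: D = removed/N and I > 0 when M > 0
  only <- increaseDecrease(N = 10, M = 6, Nthr = 7, Mthr = 6)
  expect_equal(only$D, 3 / 10)
  expect_gt(only$I, 0)
  # empty thresholded set: I undefined, D still defined
  empty <- increaseDecrease(N = 10, M = 6, Nthr = 0, Mthr = 0)
  expect_true(is.na(empty$I))
  expect_equal(empty$D, 0.4 - 0)
  expect_error(increaseDecrease(10, 6, 11, 6), "subset")
})

test_that("removed-call composition sums to one and handles empties", {
  lab <- IRanges::CharacterList(list("m", character(0), character(0),
                                    character(0)))
  comp <- filteredComposition(lab)
  expect_equal(unname(comp["nonMotif"]), 0.75)
  expect_equal(sum(comp), 1)
  allNon <- filteredComposition(IRanges::CharacterList(list(character(0))))
  expect_equal(unname(allNon["nonMotif"]), 1)
  expect_true(all(is.na(filteredComposition(IRanges::CharacterList(list())))))
})
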