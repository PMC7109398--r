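#' @importFrom stats rnorm rbeta rnbinom runif
NULL

#' Simulation configuration for synthetic 6mA datasets
#'
#' Builds the full parameter set for the synthetic-data generator. The two
#' regime presets emulate the methylation landscapes the method must
#' handle: `"prokaryote"`, where nearly all true 6mA sits on a few
#' restriction-modification motifs (> 95% of true calls on motifs), and
#' `"eukaryote"`, where methylation is weakly motif driven (< 3% of true
#' calls on motifs) and true events are outnumbered by false positives.
#' True and false calls draw their IPD ratios from well-separated truncated
#' normals; false calls are placed at random non-motif adenines.
#'
#' @param regime `"prokaryote"` or `"eukaryote"`.
#' @param seed integer RNG seed (mandatory; full determinism per seed).
#' @param genomeLength genome size in bp (default 200000, single
#'   chromosome).
#' @param gcContent GC fraction of the i.i.d. background sequence.
#' @param motifs [MotifSet-class]; regime default: GATC + GANTC
#'   (prokaryote), VATB (eukaryote).
#' @param plantCopies named integer, planted non-overlapping copies per
#'   motif (guarantees minimum motif counts on top of natural occurrences).
#' @param fracOccMethylated fraction of motif-adenine positions marked as
#'   true 6mA (prokaryote 0.95; eukaryote 0.0015, so that on-motif true
#'   calls stay below 3% of all true calls).
#' @param nTrueOffMotif count of true 6mA planted at non-motif adenines.
#' @param nFalse count of false-positive calls at random non-motif
#'   adenines.
#' @param trueIpdMean,trueIpdSd,falseIpdMean,falseIpdSd parameters of the
#'   truncated-normal IPD distributions (defaults 5.0/0.5 and 1.8/0.4).
#' @param coverageMean,coverageDispersion negative-binomial read-depth
#'   parameters (mu/size), floored at 10x.
#' @param trueFracShape,falseFracShape Beta shape pairs for the methylated
#'   fraction of true calls (mass above 0.7) and false calls.
#' @param peakWidth MeDIP peak width in bp.
#' @param peakCoverageFraction fraction of true sites guaranteed inside a
#'   peak.
#' @param decoyPeakCount off-target peaks that carry no true sites.
#' @param truePeakPassRate share of true-site peaks drawn to pass the
#'   strict peak filter (enrichment >= 1, -log10 q >= 2).
#' @param decoyPassRate share of decoy peaks drawn to pass it.
#' @param chromName chromosome identifier.
#' @return a named list of validated parameters (class
#'   `"sixmaSimConfig"`).
#' @seealso [simulateDataset()]
#' @export
simulationConfig <- function(regime = c("prokaryote", "eukaryote"),
                             seed,
                             genomeLength = 200000L,
                             gcContent = 0.5,
                             motifs = NULL,
                             plantCopies = NULL,
                             fracOccMethylated = NULL,
                             nTrueOffMotif = NULL,
                             nFalse = NULL,
                             trueIpdMean = 5.0, trueIpdSd = 0.5,
                             falseIpdMean = 1.8, falseIpdSd = 0.4,
                             coverageMean = 100, coverageDispersion = 10,
                             trueFracShape = c(12, 3),
                             falseFracShape = c(2.5, 2.5),
                             peakWidth = 500L,
                             peakCoverageFraction = NULL,
                             decoyPeakCount = 25L,
                             truePeakPassRate = 0.95,
                             decoyPassRate = 0.05,
                             chromName = "chr1") {
  regime <- match.arg(regime)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (genomeLength < 1000) stop("genomeLength must be >= 1 kb")
  if (gcContent < 0 || gcContent > 1) stop("gcContent must be in [0, 1]")
  if (regime == "prokaryote") {
    if (is.null(motifs))
      motifs <- MotifSet(c("GATC", "GANTC"), c("GATC", "GANTC"), c(1L, 1L))
    if (is.null(plantCopies))
      plantCopies <- stats::setNames(rep(100L, length(motifs)), names(motifs))
    if (is.null(fracOccMethylated)) fracOccMethylated <- 0.95
    if (is.null(nTrueOffMotif)) nTrueOffMotif <- 170L
    if (is.null(nFalse)) nFalse <- 1500L
    if (is.null(peakCoverageFraction)) peakCoverageFraction <- 0.9
  } else {
    if (is.null(motifs)) motifs <- MotifSet("VATB", "VATB", NA_integer_)
    if (is.null(plantCopies))
      plantCopies <- stats::setNames(rep(50L, length(motifs)), names(motifs))
    if (is.null(fracOccMethylated)) fracOccMethylated <- 0.0015
    if (is.null(nTrueOffMotif)) nTrueOffMotif <- 1200L
    if (is.null(nFalse)) nFalse <- 4000L
    if (is.null(peakCoverageFraction)) peakCoverageFraction <- 0.8
  }
  probs <- c(fracOccMethylated, peakCoverageFraction, truePeakPassRate,
             decoyPassRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (trueIpdMean <= falseIpdMean)
    warning("true IPD mean does not exceed the false IPD mean; ",
            "the threshold cannot separate the components")
  cfg <- list(
    regime = regime, seed = as.integer(seed), chromName = chromName,
    genomeLength = as.integer(genomeLength), gcContent = gcContent,
    motifs = motifs, plantCopies = plantCopies,
    fracOccMethylated = fracOccMethylated,
    nTrueOffMotif = as.integer(nTrueOffMotif), nFalse = as.integer(nFalse),
    trueIpdMean = trueIpdMean, trueIpdSd = trueIpdSd,
    falseIpdMean = falseIpdMean, falseIpdSd = falseIpdSd,
    coverageMean = coverageMean, coverageDispersion = coverageDispersion,
    trueFracShape = trueFracShape, falseFracShape = falseFracShape,
    peakWidth = as.integer(peakWidth),
    peakCoverageFraction = peakCoverageFraction,
    decoyPeakCount = as.integer(decoyPeakCount),
    truePeakPassRate = truePeakPassRate, decoyPassRate = decoyPassRate
  )
  class(cfg) <- "sixmaSimConfig"
  cfg
}

#' @export
print.sixmaSimConfig <- function(x, ...) {
  cat(sprintf("sixmaSimConfig: %s-like regime, %d bp genome, seed %d\n",
              x$regime, x$genomeLength, x$seed))
  cat(sprintf("  motifs: %s\n",
              paste(names(x$motifs), collapse = ", ")))
  cat(sprintf("  true IPD ~ N(%.1f, %.2f^2), false IPD ~ N(%.1f, %.2f^2)\n",
              x$trueIpdMean, x$trueIpdSd, x$falseIpdMean, x$falseIpdSd))
  invisible(x)
}

#' Generate a random background genome
#'
#' I.i.d. bases at the configured GC content; deterministic per seed.
#'
#' @param config a [simulationConfig()].
#' @return a `DNAStringSet` with one chromosome.
#' @export
generateGenome <- function(config) {
  p <- c(A = (1 - config$gcContent) / 2, C = config$gcContent / 2,
         G = config$gcContent / 2, T = (1 - config$gcContent) / 2)
  bases <- withSeed(childSeed(config$seed, 1),
                    sample(names(p), config$genomeLength, replace = TRUE,
                           prob = p))
  g <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(g) <- config$chromName
  g
}

# draw from N(mean, sd) truncated to (0, Inf) by redrawing
rnormPos <- function(n, mean, sd) {
  v <- stats::rnorm(n, mean, sd)
  while (any(bad <- v <= 0)) v[bad] <- stats::rnorm(sum(bad), mean, sd)
  v
}

# modification QV as a monotone function of IPD elevation and depth,
# clipped to the realistic 1..60 range
scoreFromKinetics <- function(ipd, coverage) {
  pmin(60, pmax(1, round(8 * (ipd - 1) + 0.05 * coverage +
                           stats::rnorm(length(ipd), 0, 2))))
}

#' Plant motifs and emit a synthetic 6mA call table with ground truth
#'
#' Overwrites the background sequence with non-overlapping concrete
#' realizations of each motif (guaranteeing the configured copy numbers),
#' then scans the final genome so that natural background occurrences are
#' also known and never mislabeled. True 6mA calls are placed on the
#' configured fraction of motif-adenine positions plus `nTrueOffMotif`
#' random non-motif adenines, with IPD ratios from the true component;
#' false-positive calls go to random non-motif adenines with IPD ratios
#' from the false component, lower scores and lower methylated fractions.
#'
#' @param genome `DNAStringSet` from [generateGenome()].
#' @param config a [simulationConfig()].
#' @return list with `genome` (motif-planted `DNAStringSet`), `calls`
#'   (call `GRanges` in position order), `truth` (data.frame: chrom,
#'   position, strand, isTrue, onMotif, motifName) and `occurrences`
#'   (the [scanMotifs()] result for the final genome).
#' @export
plantMotifsAndCalls <- function(genome, config) {
  withSeed(childSeed(config$seed, 2), {
    chromStr <- as.character(genome[[1]])
    L <- nchar(chromStr)
    motifs <- config$motifs
    # place non-overlapping concrete motif copies
    used <- IRanges::IRanges()
    for (mi in seq_along(motifs)) {
      pattern <- strsplit(motifs@pattern[mi], "")[[1]]
      wanted <- config$plantCopies[[names(motifs)[mi]]]
      placed <- 0L
      tries <- 0L
      while (placed < wanted) {
        tries <- tries + 1L
        if (tries > 50L * wanted)
          stop(sprintf("could not place %d non-overlapping copies of %s (placed %d)",
                       wanted, names(motifs)[mi], placed))
        s <- sample.int(L - length(pattern) + 1L, 1L)
        cand <- IRanges::IRanges(s, s + length(pattern) - 1L)
        if (length(IRanges::findOverlaps(cand, used)) > 0) next
        concrete <- vapply(pattern, function(ch) {
          opts <- IUPAC_CODES[[ch]]
          if (length(opts) == 1) opts else sample(opts, 1)
        }, character(1))
        substring(chromStr, s, s + length(pattern) - 1L) <-
          paste(concrete, collapse = "")
        used <- c(used, cand)
        placed <- placed + 1L
      }
    }
    planted <- Biostrings::DNAStringSet(chromStr)
    names(planted) <- names(genome)

    # scan the final sequence: natural occurrences join the ground truth
    occ <- scanMotifs(planted, motifs)
    ap <- occ$adeninePositions
    nper <- lengths(ap)
    motifAdenines <- unique(data.frame(
      position = unlist(ap),
      strand = rep(as.character(GenomicRanges::strand(occ)), nper),
      motif = rep(occ$motif, nper),
      stringsAsFactors = FALSE
    ))
    # one row per (position, strand); multiple motif names comma-joined
    key <- paste(motifAdenines$position, motifAdenines$strand)
    motifName <- vapply(split(motifAdenines$motif, key),
                        function(m) paste(sort(unique(m)), collapse = ","),
                        character(1))
    uniq <- !duplicated(key)
    motifSites <- data.frame(position = motifAdenines$position[uniq],
                             strand = motifAdenines$strand[uniq],
                             motifName = motifName[match(key[uniq],
                                                         names(motifName))],
                             stringsAsFactors = FALSE)

    # adenine universe on both strands (A forward, T reverse)
    bases <- strsplit(chromStr, "")[[1]]
    plusA <- which(bases == "A")
    minusA <- which(bases == "T")
    motifKey <- paste(motifSites$position, motifSites$strand)
    offMotif <- rbind(
      data.frame(position = plusA, strand = "+", stringsAsFactors = FALSE),
      data.frame(position = minusA, strand = "-", stringsAsFactors = FALSE)
    )
    offMotif <- offMotif[!paste(offMotif$position, offMotif$strand) %in%
                           motifKey, ]

    nTrueOn <- round(config$fracOccMethylated * nrow(motifSites))
    idxOn <- sample.int(nrow(motifSites), nTrueOn)
    need <- config$nTrueOffMotif + config$nFalse
    if (nrow(offMotif) < need)
      stop("genome too small for the requested off-motif call counts")
    idxOff <- sample.int(nrow(offMotif), need)
    trueOff <- offMotif[idxOff[seq_len(config$nTrueOffMotif)], ]
    falseSites <- offMotif[idxOff[config$nTrueOffMotif + seq_len(config$nFalse)], ]

    sites <- rbind(
      data.frame(position = motifSites$position[idxOn],
                 strand = motifSites$strand[idxOn],
                 isTrue = rep(TRUE, length(idxOn)),
                 onMotif = rep(TRUE, length(idxOn)),
                 motifName = motifSites$motifName[idxOn],
                 stringsAsFactors = FALSE),
      data.frame(position = trueOff$position, strand = trueOff$strand,
                 isTrue = rep(TRUE, nrow(trueOff)),
                 onMotif = rep(FALSE, nrow(trueOff)),
                 motifName = rep(NA_character_, nrow(trueOff)),
                 stringsAsFactors = FALSE),
      data.frame(position = falseSites$position, strand = falseSites$strand,
                 isTrue = rep(FALSE, nrow(falseSites)),
                 onMotif = rep(FALSE, nrow(falseSites)),
                 motifName = rep(NA_character_, nrow(falseSites)),
                 stringsAsFactors = FALSE)
    )
    ord <- order(sites$position, sites$strand)
    sites <- sites[ord, ]
    n <- nrow(sites)

    ipd <- numeric(n)
    frac <- numeric(n)
    ipd[sites$isTrue] <- rnormPos(sum(sites$isTrue),
                                  config$trueIpdMean, config$trueIpdSd)
    ipd[!sites$isTrue] <- rnormPos(sum(!sites$isTrue),
                                   config$falseIpdMean, config$falseIpdSd)
    coverage <- pmax(10L, stats::rnbinom(n, size = config$coverageDispersion,
                                         mu = config$coverageMean))
    frac[sites$isTrue] <- stats::rbeta(sum(sites$isTrue),
                                       config$trueFracShape[1],
                                       config$trueFracShape[2])
    frac[!sites$isTrue] <- stats::rbeta(sum(!sites$isTrue),
                                        config$falseFracShape[1],
                                        config$falseFracShape[2])
    score <- scoreFromKinetics(ipd, coverage)
    # rounded so emitted files are byte-stable and round-trip exactly
    ipd <- round(ipd, 4)
    frac <- round(frac, 3)

    calls <- modCalls(chrom = config$chromName, position = sites$position,
                      strand = sites$strand, ipdRatio = ipd,
                      coverage = coverage, score = score, fraction = frac)
    truth <- data.frame(chrom = config$chromName,
                        position = sites$position,
                        strand = sites$strand,
                        isTrue = sites$isTrue,
                        onMotif = sites$onMotif,
                        motifName = sites$motifName,
                        stringsAsFactors = FALSE)
    list(genome = planted, calls = calls, truth = truth, occurrences = occ)
  })
}

#' Simulate a MeDIP-seq peak track for a synthetic truth table
#'
#' Emits peaks of the configured width over clusters of true 6mA sites for
#' the configured coverage fraction, plus off-target decoy peaks carrying
#' no true sites. Enrichment and -log10(q) are drawn so that
#' `truePeakPassRate` of the true-site peaks pass the strict peak filter
#' (enrichment >= 1, -log10 q >= 2) while decoys mostly fail it.
#'
#' @param truth truth data.frame from [plantMotifsAndCalls()].
#' @param config a [simulationConfig()].
#' @return a peak `GRanges` in the layout of [readNarrowPeak()].
#' @export
simulatePeaks <- function(truth, config) {
  withSeed(childSeed(config$seed, 3), {
    L <- config$genomeLength
    w <- config$peakWidth
    truePos <- sort(unique(truth$position[truth$isTrue]))
    nCover <- round(config$peakCoverageFraction * length(truePos))
    covered <- sort(sample(truePos, nCover))
    starts <- integer(0)
    ends <- integer(0)
    i <- 1L
    while (i <= length(covered)) {
      # cluster sites within one peak width (20 bp margins)
      first <- covered[i]
      j <- i
      while (j < length(covered) && covered[j + 1] - first <= w - 41L)
        j <- j + 1L
      s <- max(1L, first - 20L)
      e <- min(L, max(s + w - 1L, covered[j] + 20L))
      starts <- c(starts, s)
      ends <- c(ends, e)
      i <- j + 1L
    }
    nTrue <- length(starts)
    pass <- stats::runif(nTrue) < config$truePeakPassRate
    enr <- ifelse(pass, stats::runif(nTrue, 1.5, 10),
                  stats::runif(nTrue, 0.2, 0.95))
    q <- ifelse(pass, stats::runif(nTrue, 3, 40),
                stats::runif(nTrue, 0, 1.5))
    # decoys: off-target, overwhelmingly failing the strict filter
    nDecoy <- config$decoyPeakCount
    ds <- integer(0)
    truePeaks <- IRanges::IRanges(starts, ends)
    tries <- 0L
    while (length(ds) < nDecoy && tries < 100L * nDecoy) {
      tries <- tries + 1L
      s <- sample.int(L - w, 1L)
      if (length(IRanges::findOverlaps(IRanges::IRanges(s, s + w - 1L),
                                       truePeaks)) == 0)
        ds <- c(ds, s)
    }
    dpass <- stats::runif(length(ds)) < config$decoyPassRate
    denr <- ifelse(dpass, stats::runif(length(ds), 1, 3),
                   stats::runif(length(ds), 0.2, 1.2))
    dq <- ifelse(dpass, stats::runif(length(ds), 2.5, 6),
                 stats::runif(length(ds), 0, 1.9))
    allStart <- c(starts, ds)
    allEnd <- c(ends, ds + w - 1L)
    allEnr <- c(enr, denr)
    allQ <- c(q, dq)
    ord <- order(allStart)
    gr <- GenomicRanges::GRanges(
      seqnames = config$chromName,
      ranges = IRanges::IRanges(allStart[ord], allEnd[ord]),
      strand = "*"
    )
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = paste0("peak_", seq_along(gr)),
      displayScore = round(10 * allQ[ord]),
      enrichment = round(allEnr[ord], 4),
      negLog10P = round(allQ[ord] + 0.5, 4),
      negLog10Q = round(allQ[ord], 4),
      summitOffset = as.integer(GenomicRanges::width(gr) %/% 2L)
    )
    gr
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [generateGenome()], [plantMotifsAndCalls()] and [simulatePeaks()]
#' and writes genome FASTA, modifications GFF, narrowPeak, motif TSV,
#' ground-truth TSV and a JSON manifest to `dir`. Every file is
#' byte-identical across runs with the same config.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @return (invisibly) list with the in-memory objects (`genome`, `calls`,
#'   `peaks`, `truth`, `occurrences`, `config`) and, when `dir` is given,
#'   `paths` to the written files.
#' @export
simulateDataset <- function(config, dir = NULL) {
  genome0 <- generateGenome(config)
  pl <- plantMotifsAndCalls(genome0, config)
  peaks <- simulatePeaks(pl$truth, config)
  out <- list(genome = pl$genome, calls = pl$calls, peaks = peaks,
              truth = pl$truth, occurrences = pl$occurrences,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fasta"),
      modifications = file.path(dir, "modifications.gff"),
      peaks = file.path(dir, "peaks.narrowPeak"),
      motifs = file.path(dir, "motifs.tsv"),
      truth = file.path(dir, "truth.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    writeGenome(pl$genome, paths$genome)
    writeCalls(pl$calls, paths$modifications, format = "gff")
    writeNarrowPeak(peaks, paths$peaks)
    writeMotifs(config$motifs, paths$motifs)
    utils::write.table(pl$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- list(
      regime = config$regime, seed = config$seed,
      genomeLength = config$genomeLength,
      motifs = as.list(motifPatterns(config$motifs)),
      files = lapply(paths[names(paths) != "manifest"], basename),
      nCalls = length(pl$calls), nPeaks = length(peaks)
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
    out$paths <- paths
  }
  invisible(out)
}

#' Read a ground-truth table
#'
#' @param path truth TSV written by [simulateDataset()].
#' @return data.frame with chrom, position, strand, isTrue, onMotif,
#'   motifName.
#' @export
readGroundTruth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "position", "strand", "isTrue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("truth table missing column(s): ", paste(miss, collapse = ", "))
  df
}
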