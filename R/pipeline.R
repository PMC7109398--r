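#' @importFrom utils packageVersion write.table
NULL

#' Run the full MeDIP-guided 6mA quality-control pipeline
#'
#' Executes the complete workflow on a call table and a MeDIP-seq peak
#' track: basic coverage filtering of the genome-wide calls, construction
#' of the conservative set (strict call cutoffs intersected with strictly
#' filtered peaks), sampling of its IPD ratios, derivation of the
#' lower-confidence-bound threshold, genome-wide application of the
#' threshold, and — when a genome and motif list are supplied — the
#' motif-proportion evaluation over the four analysis states (PacBio,
#' PacBio+MeDIP, PacBio+threshold, PacBio+MeDIP+threshold).
#'
#' @param modifications call `GRanges`, or path to a modifications GFF.
#' @param peaks peak `GRanges`, or path to a narrowPeak file.
#' @param genome `DNAStringSet`, or path to a FASTA file; `NULL` skips the
#'   motif evaluation.
#' @param motifs [MotifSet-class], or path to a motif TSV; `NULL` skips
#'   the motif evaluation.
#' @param seed integer RNG seed for the threshold sample (mandatory).
#' @param basicMinCoverage coverage floor of the basic genome-wide pass
#'   (default 50).
#' @param minCoverage,minScore,minFraction strict call cutoffs for the
#'   conservative set (defaults 50, 30, 0.7).
#' @param minEnrichment,minNegLog10Q strict peak cutoffs (defaults 1, 2).
#' @param n threshold sample size (default 30).
#' @param alpha significance level (default 0.05).
#' @param critical `"normal"`, `"student"` or a numeric multiplier; see
#'   [computeThreshold()].
#' @param threshold optional externally supplied IPD-ratio threshold (e.g.
#'   from a WGA-control method) used instead of deriving one; the
#'   conservative set is still built for provenance.
#' @param outDir optional output directory; when given, retained/removed
#'   call sets (GFF + BED), the threshold report (JSON), the motif tables
#'   (TSV) and a run log are written there.
#' @return a list of class `"sixmaRun"` with elements `calls` (the basic
#'   state), `states` (named list of the four state `GRanges`),
#'   `conservative` ([ConservativeSet-class]), `model`
#'   ([ThresholdModel-class] or `NULL` when `threshold` was supplied),
#'   `filter` ([FilterResult-class]), `normality`, `report`
#'   ([MotifProportionReport-class] or `NULL`), `removedComposition`,
#'   `labels` (per-state motif labels) and `provenance`.
#' @examples
#' sim <- simulateDataset(simulationConfig("prokaryote", seed = 7,
#'                                         genomeLength = 20000L,
#'                                         nFalse = 200L))
#' run <- runQC(sim$calls, sim$peaks, sim$genome, sim$config$motifs,
#'              seed = 7)
#' thresholdValue(run$model)
#' @export
runQC <- function(modifications, peaks, genome = NULL, motifs = NULL,
                  seed,
                  basicMinCoverage = 50,
                  minCoverage = 50, minScore = 30, minFraction = 0.7,
                  minEnrichment = 1, minNegLog10Q = 2,
                  n = 30, alpha = 0.05, critical = "normal",
                  threshold = NULL,
                  outDir = NULL) {
  if (is.character(modifications))
    modifications <- readModificationsGff(modifications)
  if (is.character(peaks)) peaks <- readNarrowPeak(peaks)
  if (is.character(genome)) genome <- readGenome(genome)
  if (is.character(motifs)) motifs <- readMotifs(motifs)
  if ((missing(seed) || is.null(seed)) && is.null(threshold))
    stop("a seed is required to sample the conservative set")
  if (missing(seed)) seed <- NA_integer_

  calls <- collapseDuplicateCalls(modifications)
  # basic genome-wide pass: coverage floor only
  basic <- filterCalls(calls, minCoverage = basicMinCoverage, minScore = 0,
                       minFraction = NULL)
  goodPeaks <- filterPeaks(peaks, minEnrichment, minNegLog10Q)
  conservative <- buildConservativeSet(
    basic, peaks, minCoverage = minCoverage, minScore = minScore,
    minFraction = minFraction, minEnrichment = minEnrichment,
    minNegLog10Q = minNegLog10Q)

  model <- NULL
  normality <- NULL
  if (is.null(threshold)) {
    smp <- sampleIpdRatios(conservative, n = n, seed = seed)
    normality <- withCallingHandlers(
      checkSampleNormality(smp),
      warning = function(w) {
        message("normality diagnostic: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    model <- computeThreshold(smp, alpha = alpha, critical = critical,
                              seed = seed)
    threshold <- thresholdValue(model)
  }
  filt <- applyThreshold(basic, threshold)

  states <- list(
    "PacBio" = basic,
    "PacBio+MeDIP" = intersectCallsPeaks(basic, goodPeaks),
    "PacBio+threshold" = retainedCalls(filt),
    "PacBio+MeDIP+threshold" = intersectCallsPeaks(retainedCalls(filt),
                                                   goodPeaks)
  )

  report <- NULL
  removedComposition <- NULL
  labels <- NULL
  if (!is.null(genome) && !is.null(motifs)) {
    occ <- scanMotifs(genome, motifs)
    labels <- lapply(states, classifyCalls, occurrences = occ)
    report <- computeStateProportions(labels, motifNames = names(motifs),
                                      beforeState = "PacBio",
                                      afterState = "PacBio+threshold")
    removedComposition <- filteredComposition(
      classifyCalls(removedCalls(filt), occ))
  }

  provenance <- list(
    package = as.character(utils::packageVersion("sixmaQC")),
    seed = seed,
    threshold = threshold,
    thresholdSource = if (is.null(model)) "external" else model@mode,
    cutoffs = list(basicMinCoverage = basicMinCoverage,
                   minCoverage = minCoverage, minScore = minScore,
                   minFraction = minFraction,
                   minEnrichment = minEnrichment,
                   minNegLog10Q = minNegLog10Q),
    n = n, alpha = alpha,
    counts = c(input = length(calls), basic = length(basic),
               conservative = length(conservative),
               retained = length(retainedCalls(filt)),
               removed = length(removedCalls(filt)))
  )

  run <- list(calls = basic, states = states, conservative = conservative,
              model = model, filter = filt, normality = normality,
              report = report, removedComposition = removedComposition,
              labels = labels, provenance = provenance)
  class(run) <- "sixmaRun"
  if (!is.null(outDir)) writeRunOutputs(run, outDir)
  run
}

#' @export
print.sixmaRun <- function(x, ...) {
  cat("sixmaQC run\n")
  cat(sprintf("  IPD-ratio threshold: %.4f (%s)\n", x$provenance$threshold,
              x$provenance$thresholdSource))
  cnt <- x$provenance$counts
  cat(sprintf("  calls: %d input, %d basic, %d conservative, %d retained, %d removed\n",
              cnt["input"], cnt["basic"], cnt["conservative"],
              cnt["retained"], cnt["removed"]))
  if (!is.null(x$report)) {
    cat(sprintf("  total-motif increase I = %.4f, non-motif decrease D = %.4f\n",
                motifIncrease(x$report), nonMotifDecrease(x$report)))
  }
  invisible(x)
}

writeRunOutputs <- function(run, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeCalls(retainedCalls(run$filter), file.path(outDir, "retained.gff"),
             "gff")
  writeCalls(removedCalls(run$filter), file.path(outDir, "removed.gff"),
             "gff")
  writeCalls(retainedCalls(run$filter), file.path(outDir, "retained.bed"),
             "bed")
  rep <- list(
    threshold = run$provenance$threshold,
    thresholdSource = run$provenance$thresholdSource,
    seed = run$provenance$seed,
    n = run$provenance$n,
    alpha = run$provenance$alpha,
    cutoffs = run$provenance$cutoffs,
    counts = as.list(run$provenance$counts)
  )
  if (!is.null(run$model)) {
    rep$sampleMean <- sampleMean(run$model)
    rep$sampleSD <- sampleSD(run$model)
    rep$criticalValue <- run$model@criticalValue
  }
  if (!is.null(run$normality)) rep$normality <- run$normality
  jsonlite::write_json(rep, file.path(outDir, "threshold_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(run$report)) {
    utils::write.table(perMotifTable(run$report),
                       file.path(outDir, "motif_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tot <- totalsTable(run$report)
    tot$I <- motifIncrease(run$report)
    tot$D <- nonMotifDecrease(run$report)
    utils::write.table(tot, file.path(outDir, "motif_totals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- c(
    paste0("sixmaQC ", utils::packageVersion("sixmaQC")),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", run$provenance$seed),
    paste0("threshold: ", run$provenance$threshold),
    paste0("cutoffs: ", paste(names(run$provenance$cutoffs),
                              unlist(run$provenance$cutoffs),
                              sep = "=", collapse = ", ")),
    paste0("counts: ", paste(names(run$provenance$counts),
                             run$provenance$counts,
                             sep = "=", collapse = ", "))
  )
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(outDir)
}

#' Evaluate a run against ground truth
#'
#' Scores the IPD-ratio threshold filter against a ground-truth table from
#' the synthetic generator: sensitivity (true sites retained), specificity
#' (false calls removed) and precision (retained calls that are true).
#' Undefined ratios (empty retained set) are reported as `NA`.
#'
#' @param run a `"sixmaRun"` from [runQC()], or a
#'   [FilterResult-class].
#' @param truth truth data.frame (see [readGroundTruth()]) or a path to a
#'   truth TSV.
#' @return list with `sensitivity`, `specificity`, `precision` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluateRun <- function(run, truth) {
  if (is.character(truth)) truth <- readGroundTruth(truth)
  filt <- if (inherits(run, "sixmaRun")) run$filter else run
  stopifnot(is(filt, "FilterResult"))
  truthKey <- paste(truth$chrom, truth$position, truth$strand)
  keyOf <- function(gr) paste(as.character(GenomicRanges::seqnames(gr)),
                              GenomicRanges::start(gr),
                              as.character(GenomicRanges::strand(gr)))
  retKey <- keyOf(retainedCalls(filt))
  remKey <- keyOf(removedCalls(filt))
  miss <- c(retKey, remKey)[!c(retKey, remKey) %in% truthKey]
  if (length(miss))
    stop(length(miss), " call(s) not present in the ground-truth table")
  isTrue <- stats::setNames(truth$isTrue, truthKey)
  tp <- sum(isTrue[retKey])
  fp <- sum(!isTrue[retKey])
  fn <- sum(isTrue[remKey])
  tn <- sum(!isTrue[remKey])
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}
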