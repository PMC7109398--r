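#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits
NULL

#' Filter MeDIP-seq peaks on enrichment and q-value
#'
#' Keeps peaks with fold enrichment and -log10(q) at or above the cutoffs
#' (inclusive). The defaults are the strict peak filter used to build the
#' conservative set: enrichment >= 1 and -log10(q) >= 2 (q <= 0.01).
#'
#' @param peaks peak `GRanges` from [readNarrowPeak()].
#' @param minEnrichment minimum fold enrichment (default 1).
#' @param minNegLog10Q minimum -log10(q) (default 2).
#' @return the retained peaks, input order preserved.
#' @export
filterPeaks <- function(peaks, minEnrichment = 1, minNegLog10Q = 2) {
  if (minEnrichment < 0 || minNegLog10Q < 0)
    stop("peak cutoffs must be non-negative")
  peaks[peaks$enrichment >= minEnrichment & peaks$negLog10Q >= minNegLog10Q]
}

#' Filter modification calls on coverage, score and fraction
#'
#' All comparisons are inclusive (>=). The strict defaults (coverage >= 50,
#' score >= 30, fraction >= 0.7) define the call side of the conservative
#' set; the basic genome-wide pass uses `minScore = 0`,
#' `minFraction = NULL` so that only the coverage floor applies. Calls with
#' an absent (`NA`) fraction fail any finite `minFraction`.
#'
#' @param calls call `GRanges`.
#' @param minCoverage minimum read depth (default 50).
#' @param minScore minimum modification QV (default 30).
#' @param minFraction minimum methylated fraction in \[0, 1\], or `NULL` to
#'   skip the fraction cutoff (default 0.7).
#' @param perChromosomeCoverage if `TRUE`, instead of the per-site coverage
#'   cutoff, drop every call on chromosomes whose mean call coverage is
#'   below `minCoverage` (an alternative reading of the coverage rule;
#'   default `FALSE`, the per-site reading).
#' @return the retained calls, input order preserved.
#' @export
filterCalls <- function(calls, minCoverage = 50, minScore = 30,
                        minFraction = 0.7, perChromosomeCoverage = FALSE) {
  if (!is.null(minFraction) &&
      (is.na(minFraction) || minFraction < 0 || minFraction > 1))
    stop("minFraction must be in [0, 1] or NULL")
  if (minCoverage < 0 || minScore < 0)
    stop("call cutoffs must be non-negative")
  if (length(calls) == 0) return(calls)
  if (perChromosomeCoverage) {
    chrom <- as.character(GenomicRanges::seqnames(calls))
    meanCov <- tapply(calls$coverage, chrom, mean)
    keep <- meanCov[chrom] >= minCoverage
  } else {
    keep <- calls$coverage >= minCoverage
  }
  keep <- keep & calls$score >= minScore
  if (!is.null(minFraction))
    keep <- keep & !is.na(calls$fraction) & calls$fraction >= minFraction
  calls[keep]
}

#' Collapse duplicate calls
#'
#' Calls sharing chromosome, position and strand would double-count in the
#' motif proportion statistics; duplicates after the first are dropped with
#' a warning.
#'
#' @param calls call `GRanges`.
#' @return calls with duplicates removed, first occurrence kept.
#' @export
collapseDuplicateCalls <- function(calls) {
  if (length(calls) < 2) return(calls)
  key <- paste(as.character(GenomicRanges::seqnames(calls)),
               GenomicRanges::start(calls),
               as.character(GenomicRanges::strand(calls)))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate call(s) (same chrom, position, strand) collapsed")
    calls <- calls[!dup]
  }
  calls
}

#' Intersect calls with peak regions
#'
#' Returns the calls whose position falls inside at least one peak on the
#' same chromosome. MeDIP peaks are unstranded, so peak strand is ignored
#' while call strand is retained. A call present in several overlapping
#' peaks is returned once; input order is preserved. Peak ends are
#' exclusive in the original BED sense: a call at 1-based position p is
#' inside BED peak [s, e) iff s <= p-1 < e, which is exactly containment
#' in the 1-based range (s+1)..e used here.
#'
#' @param calls call `GRanges`.
#' @param peaks peak `GRanges`.
#' @return the subset of `calls` overlapping any peak.
#' @export
intersectCallsPeaks <- function(calls, peaks) {
  if (length(calls) == 0 || length(peaks) == 0) return(calls[integer(0)])
  hits <- GenomicRanges::findOverlaps(calls, peaks, ignore.strand = TRUE)
  calls[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Build the conservative 6mA set
#'
#' Composition of the three strict filters: peaks are filtered on
#' enrichment and -log10(q), calls on coverage/score/fraction, and the
#' surviving calls are intersected with the surviving peaks. The result is
#' the conservative set whose IPD ratios are sampled to derive the
#' threshold; every cutoff is recorded as provenance.
#'
#' @param calls call `GRanges` (duplicates are collapsed with a warning).
#' @param peaks peak `GRanges`.
#' @param minCoverage,minScore,minFraction strict call cutoffs, see
#'   [filterCalls()].
#' @param minEnrichment,minNegLog10Q strict peak cutoffs, see
#'   [filterPeaks()].
#' @param perChromosomeCoverage see [filterCalls()].
#' @return a [ConservativeSet-class].
#' @examples
#' calls <- modCalls("chr1", c(120L, 500L), "+", c(5.0, 4.8),
#'                   coverage = 80L, score = 40, fraction = 0.9)
#' peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' peaks$name <- "p1"; peaks$displayScore <- 0
#' peaks$enrichment <- 5; peaks$negLog10P <- 10; peaks$negLog10Q <- 8
#' peaks$summitOffset <- -1L
#' buildConservativeSet(calls, peaks)
#' @export
buildConservativeSet <- function(calls, peaks,
                                 minCoverage = 50, minScore = 30,
                                 minFraction = 0.7,
                                 minEnrichment = 1, minNegLog10Q = 2,
                                 perChromosomeCoverage = FALSE) {
  calls <- collapseDuplicateCalls(calls)
  goodPeaks <- filterPeaks(peaks, minEnrichment, minNegLog10Q)
  goodCalls <- filterCalls(calls, minCoverage, minScore, minFraction,
                           perChromosomeCoverage)
  kept <- intersectCallsPeaks(goodCalls, goodPeaks)
  new("ConservativeSet", calls = kept, peaks = goodPeaks,
      cutoffs = list(minCoverage = minCoverage, minScore = minScore,
                     minFraction = minFraction,
                     minEnrichment = minEnrichment,
                     minNegLog10Q = minNegLog10Q,
                     perChromosomeCoverage = perChromosomeCoverage))
}
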