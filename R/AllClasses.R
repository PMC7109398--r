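#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' MotifSet: a collection of IUPAC degenerate motif patterns
#'
#' Holds named degenerate nucleotide patterns together with the 0-based
#' offset of the methylated adenine within each pattern. An `NA` offset
#' means "any": every pattern position whose IUPAC code is compatible with
#' adenine is a candidate methylation site.
#'
#' @slot name character vector of unique motif names.
#' @slot pattern character vector of IUPAC patterns (A,C,G,T,R,Y,S,W,K,M,
#'   B,D,H,V,N).
#' @slot methylatedOffset integer vector, 0-based index of the methylated A
#'   in the pattern, or `NA` for "any A-compatible position".
#'
#' @seealso [MotifSet()], [readMotifs()], [scanMotifs()]
#' @export
setClass("MotifSet",
  representation(
    name = "character",
    pattern = "character",
    methylatedOffset = "integer"
  )
)

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# IUPAC codes whose set contains A: a methylated adenine is possible there
A_COMPATIBLE <- c("A", "R", "W", "M", "D", "H", "V", "N")

setValidity("MotifSet", function(object) {
  msgs <- character()
  n <- length(object@name)
  if (length(object@pattern) != n || length(object@methylatedOffset) != n)
    msgs <- c(msgs, "name, pattern and methylatedOffset must have equal length")
  if (anyDuplicated(object@name))
    msgs <- c(msgs, "motif names must be unique")
  if (any(!nzchar(object@pattern)))
    msgs <- c(msgs, "patterns must be non-empty")
  bad <- vapply(object@pattern, function(p) {
    any(!strsplit(p, "")[[1]] %in% names(IUPAC_CODES))
  }, logical(1))
  if (any(bad))
    msgs <- c(msgs, paste0("non-IUPAC character in pattern(s): ",
                           paste(object@pattern[bad], collapse = ", ")))
  if (length(msgs) == 0 && n > 0) {
    for (i in seq_len(n)) {
      off <- object@methylatedOffset[i]
      if (!is.na(off)) {
        chars <- strsplit(object@pattern[i], "")[[1]]
        if (off < 0 || off >= length(chars))
          msgs <- c(msgs, sprintf("methylatedOffset %d out of range for pattern %s",
                                  off, object@pattern[i]))
        else if (!chars[off + 1] %in% A_COMPATIBLE)
          msgs <- c(msgs, sprintf(
            "methylatedOffset %d of pattern %s is '%s', not compatible with A",
            off, object@pattern[i], chars[off + 1]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MotifSet
#'
#' @param name character vector of motif names.
#' @param pattern character vector of IUPAC degenerate patterns.
#' @param methylatedOffset integer vector (0-based offset of the methylated
#'   adenine) or `NA` for "any A-compatible position" (the default).
#' @return A [MotifSet-class] object.
#' @examples
#' MotifSet(c("dam", "vatb"), c("GATC", "VATB"), c(1L, NA))
#' @export
MotifSet <- function(name, pattern, methylatedOffset = NA_integer_) {
  pattern <- toupper(as.character(pattern))
  methylatedOffset <- suppressWarnings(as.integer(methylatedOffset))
  methylatedOffset <- rep_len(methylatedOffset, length(name))
  new("MotifSet", name = as.character(name), pattern = pattern,
      methylatedOffset = methylatedOffset)
}

#' @describeIn MotifSet-class number of motifs
#' @param x a `MotifSet`
#' @export
setMethod("length", "MotifSet", function(x) length(x@name))

#' @describeIn MotifSet-class subset motifs
#' @param i index
#' @param j,...,drop ignored
#' @export
setMethod("[", "MotifSet", function(x, i, j, ..., drop = TRUE) {
  new("MotifSet", name = x@name[i], pattern = x@pattern[i],
      methylatedOffset = x@methylatedOffset[i])
})

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet with %d motif(s)\n", length(object)))
  if (length(object)) {
    off <- ifelse(is.na(object@methylatedOffset), "any",
                  as.character(object@methylatedOffset))
    print(data.frame(name = object@name, pattern = object@pattern,
                     methylatedOffset = off, row.names = NULL))
  }
})

#' @describeIn MotifSet-class motif names
#' @export
setMethod("names", "MotifSet", function(x) x@name)

#' Motif patterns of a MotifSet
#' @param x a [MotifSet-class]
#' @return character vector of IUPAC patterns, named by motif name.
#' @export
motifPatterns <- function(x) stats::setNames(x@pattern, x@name)

#' ConservativeSet: strictly filtered calls inside strictly filtered peaks
#'
#' The conservative 6mA set: modification calls that pass the strict
#' kinetics cutoffs (coverage, score, fraction) *and* lie inside a MeDIP-seq
#' peak that passes the strict peak cutoffs (enrichment, -log10 q). Its IPD
#' ratios are the sampling population for the threshold.
#'
#' @slot calls `GRanges` of retained calls (width-1, with ipdRatio,
#'   coverage, score, fraction metadata columns).
#' @slot peaks `GRanges` of the filtered peaks used for the intersection.
#' @slot cutoffs named list recording every cutoff applied (provenance).
#'
#' @seealso [buildConservativeSet()], [sampleIpdRatios()]
#' @export
setClass("ConservativeSet",
  representation(calls = "GRanges", peaks = "GRanges", cutoffs = "list")
)

setValidity("ConservativeSet", function(object) {
  msgs <- validateCallRanges(object@calls)
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConservativeSet", function(object) {
  cat(sprintf("ConservativeSet: %d call(s) inside %d filtered peak(s)\n",
              length(object@calls), length(object@peaks)))
  if (length(object@cutoffs)) {
    cat("cutoffs: ",
        paste(names(object@cutoffs),
              vapply(object@cutoffs, function(v)
                if (is.null(v)) "none" else format(v), character(1)),
              sep = "=", collapse = ", "), "\n")
  }
})

#' @describeIn ConservativeSet-class number of calls in the set
#' @param x a `ConservativeSet`
#' @export
setMethod("length", "ConservativeSet", function(x) length(x@calls))

#' Accessors for ConservativeSet
#'
#' @param x a [ConservativeSet-class]
#' @return `conservativeCalls()`: the call `GRanges`; `conservativePeaks()`:
#'   the filtered peak `GRanges`; `cutoffsUsed()`: the named cutoff list.
#' @export
conservativeCalls <- function(x) {
  stopifnot(is(x, "ConservativeSet"))
  x@calls
}

#' @rdname conservativeCalls
#' @export
conservativePeaks <- function(x) {
  stopifnot(is(x, "ConservativeSet"))
  x@peaks
}

#' @rdname conservativeCalls
#' @export
cutoffsUsed <- function(x) {
  stopifnot(is(x, "ConservativeSet"))
  x@cutoffs
}

#' ThresholdModel: IPD-ratio threshold from a confidence interval
#'
#' Summarises a random sample of IPD ratios from the conservative set and
#' the derived threshold: the lower bound of the two-sided confidence
#' interval for the population mean,
#' \deqn{\bar{X} - t_{\alpha/2}(n-1) \, S/\sqrt{n},}
#' with \eqn{S} the sample standard deviation (n-1 denominator).
#'
#' @slot sampleValues numeric, the sampled IPD ratios.
#' @slot n integer sample size (default 30 in the pipeline).
#' @slot alpha numeric significance level (default 0.05).
#' @slot criticalValue numeric multiplier actually used (1.96 in "normal"
#'   mode; the exact Student quantile in "student" mode).
#' @slot mode character, "normal", "student" or "fixed".
#' @slot sampleMean,sampleSD numeric summaries of the sample.
#' @slot threshold numeric, the derived IPD-ratio threshold.
#' @slot seed integer RNG seed used for the draw, or `NULL` when the sample
#'   was supplied directly.
#'
#' @seealso [computeThreshold()], [applyThreshold()]
#' @export
setClass("ThresholdModel",
  representation(
    sampleValues = "numeric",
    n = "integer",
    alpha = "numeric",
    criticalValue = "numeric",
    mode = "character",
    sampleMean = "numeric",
    sampleSD = "numeric",
    threshold = "numeric",
    seed = "integerOrNULL"
  )
)

setValidity("ThresholdModel", function(object) {
  msgs <- character()
  if (object@n < 2L) msgs <- c(msgs, "sample size n must be >= 2")
  if (length(object@sampleValues) != object@n)
    msgs <- c(msgs, "length(sampleValues) must equal n")
  if (any(object@sampleValues <= 0))
    msgs <- c(msgs, "IPD ratios must be positive")
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must be in (0, 1)")
  # lower confidence bound never exceeds the mean; equal only when S = 0
  if (object@threshold > object@sampleMean + 1e-12)
    msgs <- c(msgs, "threshold must not exceed the sample mean")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ThresholdModel", function(object) {
  cat("ThresholdModel\n")
  cat(sprintf("  n = %d, alpha = %g, critical = %.4f (%s mode)\n",
              object@n, object@alpha, object@criticalValue, object@mode))
  cat(sprintf("  sample mean = %.4f, sd = %.4f\n",
              object@sampleMean, object@sampleSD))
  cat(sprintf("  IPD-ratio threshold = %.4f\n", object@threshold))
  if (!is.null(object@seed)) cat(sprintf("  seed = %d\n", object@seed))
})

#' Accessors for ThresholdModel
#'
#' @param x a [ThresholdModel-class]
#' @return `thresholdValue()`: the derived threshold; `sampleMean()` /
#'   `sampleSD()`: the sample summaries; `sampleValues()`: the raw sampled
#'   IPD ratios.
#' @export
thresholdValue <- function(x) {
  stopifnot(is(x, "ThresholdModel"))
  x@threshold
}

#' @rdname thresholdValue
#' @export
sampleMean <- function(x) {
  stopifnot(is(x, "ThresholdModel"))
  x@sampleMean
}

#' @rdname thresholdValue
#' @export
sampleSD <- function(x) {
  stopifnot(is(x, "ThresholdModel"))
  x@sampleSD
}

#' @rdname thresholdValue
#' @export
sampleValues <- function(x) {
  stopifnot(is(x, "ThresholdModel"))
  x@sampleValues
}

#' FilterResult: partition of calls at an IPD-ratio threshold
#'
#' The result of applying an IPD-ratio threshold to a call set: calls with
#' `ipdRatio >= threshold` are retained (the quality-controlled set), the
#' rest are removed as putative false positives.
#'
#' @slot thresholdUsed numeric threshold.
#' @slot retained,removed `GRanges` partition of the input (input order
#'   preserved in each part).
#' @slot nInput integer, total number of input calls.
#'
#' @seealso [applyThreshold()]
#' @export
setClass("FilterResult",
  representation(
    thresholdUsed = "numeric",
    retained = "GRanges",
    removed = "GRanges",
    nInput = "integer"
  )
)

setValidity("FilterResult", function(object) {
  msgs <- character()
  if (length(object@retained) + length(object@removed) != object@nInput)
    msgs <- c(msgs, "retained + removed must partition the input")
  if (length(object@retained) &&
      any(object@retained$ipdRatio < object@thresholdUsed))
    msgs <- c(msgs, "every retained call must have ipdRatio >= threshold")
  if (length(object@removed) &&
      any(object@removed$ipdRatio >= object@thresholdUsed))
    msgs <- c(msgs, "every removed call must have ipdRatio < threshold")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FilterResult", function(object) {
  cat(sprintf("FilterResult: threshold %.4f; %d/%d call(s) retained, %d removed\n",
              object@thresholdUsed, length(object@retained), object@nInput,
              length(object@removed)))
})

#' Accessors for FilterResult
#'
#' @param x a [FilterResult-class]
#' @return `retainedCalls()` / `removedCalls()`: the two `GRanges` parts;
#'   `thresholdUsed()`: the threshold that produced the partition.
#' @export
retainedCalls <- function(x) {
  stopifnot(is(x, "FilterResult"))
  x@retained
}

#' @rdname retainedCalls
#' @export
removedCalls <- function(x) {
  stopifnot(is(x, "FilterResult"))
  x@removed
}

#' @rdname retainedCalls
#' @export
thresholdUsed <- function(x) {
  stopifnot(is(x, "FilterResult"))
  x@thresholdUsed
}

#' MotifProportionReport: per-motif and total-motif proportions
#'
#' Per-motif proportions of 6mA calls in up to four analysis states
#' (unfiltered SMRT calls; calls in MeDIP peaks; calls above the IPD
#' threshold; calls in peaks and above the threshold) plus the total-motif
#' increase I and non-motif decrease D between the unfiltered and
#' thresholded states.
#'
#' @slot perMotif data.frame with columns motif, state, m (calls on that
#'   motif), N (calls in the state), proportion (m/N, `NA` when N = 0).
#' @slot totals data.frame with columns state, M (calls on any motif), N,
#'   proportion (M/N).
#' @slot increase numeric I = M_thr/N_thr - M/N (`NA` when undefined).
#' @slot decrease numeric D = (1 - M/N) - (N_thr - M_thr)/N.
#'
#' @seealso [computeStateProportions()], [increaseDecrease()]
#' @export
setClass("MotifProportionReport",
  representation(
    perMotif = "data.frame",
    totals = "data.frame",
    increase = "numeric",
    decrease = "numeric"
  )
)

setMethod("show", "MotifProportionReport", function(object) {
  cat("MotifProportionReport\n")
  cat("totals per state:\n")
  print(object@totals, row.names = FALSE)
  if (!is.na(object@increase))
    cat(sprintf("total-motif increase I = %.4f\n", object@increase))
  if (!is.na(object@decrease))
    cat(sprintf("non-motif decrease D = %.4f\n", object@decrease))
})

#' Accessors for MotifProportionReport
#'
#' @param x a [MotifProportionReport-class]
#' @return `perMotifTable()` / `totalsTable()`: the tidy data.frames;
#'   `motifIncrease()` / `nonMotifDecrease()`: the I and D statistics.
#' @export
perMotifTable <- function(x) {
  stopifnot(is(x, "MotifProportionReport"))
  x@perMotif
}

#' @rdname perMotifTable
#' @export
totalsTable <- function(x) {
  stopifnot(is(x, "MotifProportionReport"))
  x@totals
}

#' @rdname perMotifTable
#' @export
motifIncrease <- function(x) {
  stopifnot(is(x, "MotifProportionReport"))
  x@increase
}

#' @rdname perMotifTable
#' @export
nonMotifDecrease <- function(x) {
  stopifnot(is(x, "MotifProportionReport"))
  x@decrease
}
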