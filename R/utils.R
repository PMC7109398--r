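#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

# Required metadata columns of a call GRanges; positions are width-1 ranges
# in 1-based coordinates (GRanges native).
CALL_MCOLS <- c("modType", "ipdRatio", "coverage", "score", "fraction")
PEAK_MCOLS <- c("name", "displayScore", "enrichment", "negLog10P",
                "negLog10Q", "summitOffset")

# Internal validator shared by readers, constructors and class validity.
# Returns a character vector of problems (empty when valid).
validateCallRanges <- function(gr) {
  msgs <- character()
  if (!is(gr, "GRanges")) return("calls must be a GRanges")
  miss <- setdiff(CALL_MCOLS, names(S4Vectors::mcols(gr)))
  if (length(miss))
    return(paste0("missing call column(s): ", paste(miss, collapse = ", ")))
  if (length(gr) == 0) return(msgs)
  if (any(GenomicRanges::width(gr) != 1L))
    msgs <- c(msgs, "calls must be width-1 ranges")
  if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
    msgs <- c(msgs, "call strand must be + or -")
  if (any(!is.finite(gr$ipdRatio)) || any(gr$ipdRatio <= 0))
    msgs <- c(msgs, "ipdRatio must be finite and > 0")
  if (any(gr$coverage < 0)) msgs <- c(msgs, "coverage must be >= 0")
  if (any(gr$score < 0)) msgs <- c(msgs, "score must be >= 0")
  fr <- gr$fraction
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    msgs <- c(msgs, "fraction must be in [0, 1] when present")
  msgs
}

#' Construct a modification-call GRanges
#'
#' Builds the width-1 `GRanges` used throughout the package for putative
#' 6mA sites, with the kinetics feature columns validated: `ipdRatio` > 0,
#' `coverage` >= 0, `score` >= 0 (a Phred-type modification QV) and
#' `fraction` in \[0, 1\] or `NA` when the estimated methylated fraction is
#' unavailable.
#'
#' @param chrom character chromosome identifiers.
#' @param position integer 1-based reference coordinates of the called
#'   adenines.
#' @param strand "+" or "-".
#' @param ipdRatio positive numeric IPD ratios.
#' @param coverage non-negative integer read depths.
#' @param score non-negative modification QVs.
#' @param fraction methylated read fractions in \[0, 1\], `NA` allowed.
#' @param modType modification label, default "m6A".
#' @return a `GRanges` with metadata columns modType, ipdRatio, coverage,
#'   score, fraction.
#' @examples
#' modCalls("chr1", c(101L, 250L), c("+", "-"), c(5.1, 1.7),
#'          coverage = c(80L, 60L), score = c(40, 12), fraction = c(0.9, NA))
#' @export
modCalls <- function(chrom, position, strand, ipdRatio, coverage, score,
                     fraction = NA_real_, modType = "m6A") {
  n <- length(position)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(as.character(chrom), n),
    ranges = IRanges::IRanges(start = as.integer(position), width = 1L),
    strand = rep_len(as.character(strand), n)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    modType = rep_len(as.character(modType), n),
    ipdRatio = rep_len(as.numeric(ipdRatio), n),
    coverage = rep_len(as.integer(coverage), n),
    score = rep_len(as.numeric(score), n),
    fraction = rep_len(as.numeric(fraction), n)
  )
  msgs <- validateCallRanges(gr)
  if (length(msgs)) stop("invalid calls: ", paste(msgs, collapse = "; "))
  gr
}

#' Phred-type score and q-value transforms
#'
#' The modification score emitted by the SMRT modification caller is a
#' Phred-type quality value, QV = -10 log10(p): a score of 20 corresponds
#' to p = 0.01 and a score of 30 to p = 0.001. MACS2 narrowPeak files carry
#' q-values as -log10(q): 1.3 corresponds to q = 0.05 and 2 to q = 0.01.
#'
#' @param score modification QV.
#' @param p,q probabilities in (0, 1].
#' @param neglog10q -log10-transformed q-value.
#' @return the transformed value.
#' @examples
#' pvalueFromScore(30)        # 0.001
#' scoreFromPvalue(0.01)      # 20
#' qvalueFromNegLog10(2)      # 0.01
#' negLog10FromQvalue(0.05)   # 1.30103
#' @export
pvalueFromScore <- function(score) 10^(-score / 10)

#' @rdname pvalueFromScore
#' @export
scoreFromPvalue <- function(p) -10 * log10(p)

#' @rdname pvalueFromScore
#' @export
qvalueFromNegLog10 <- function(neglog10q) 10^(-neglog10q)

#' @rdname pvalueFromScore
#' @export
negLog10FromQvalue <- function(q) -log10(q)

# Run expr with the RNG seeded at `seed`, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# Derive a bounded child seed from a parent seed (stays well below 2^31).
childSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}
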