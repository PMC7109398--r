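#' @importFrom Biostrings matchPattern reverseComplement DNAString
#' @importFrom IRanges CharacterList IntegerList
NULL

#' Scan a genome for IUPAC degenerate motif occurrences
#'
#' Finds every position on both strands where a motif pattern matches under
#' IUPAC semantics. Ambiguity codes in the pattern are interpreted
#' (V = A/C/G, B = C/G/T, ...), but N in the reference never matches
#' anything (conservative). Minus-strand occurrences are found by matching
#' the reverse complement of the pattern on the forward sequence, with
#' coordinates reported on the forward strand. Overlapping and
#' self-overlapping occurrences are all reported.
#'
#' For each occurrence the candidate methylated-adenine coordinates are
#' recorded: with `methylatedOffset = NA` ("any"), every pattern position
#' whose IUPAC code is compatible with A and whose strand-specific
#' reference base actually is A (i.e. A on the forward strand for a `+`
#' occurrence, T for a `-` occurrence); a specific offset restricts this to
#' that single pattern position.
#'
#' @param genome a `DNAStringSet` from [readGenome()].
#' @param motifs a [MotifSet-class].
#' @return a `GRanges` of occurrences with metadata columns `motif` (name)
#'   and `adeninePositions` (`IntegerList` of 1-based reference
#'   coordinates).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "GGATCC"))
#' scanMotifs(g, MotifSet("dam", "GATC"))
#' @export
scanMotifs <- function(genome, motifs) {
  stopifnot(is(motifs, "MotifSet"))
  validObject(motifs)
  out <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    chromSeq <- genome[[ci]]
    chromStr <- as.character(chromSeq)
    for (mi in seq_along(motifs)) {
      pattern <- motifs@pattern[mi]
      chars <- strsplit(pattern, "")[[1]]
      L <- length(chars)
      if (L > length(chromSeq)) next
      off <- motifs@methylatedOffset[mi]
      # candidate pattern indices (1-based) where a methylated A can sit
      candIdx <- if (is.na(off)) which(chars %in% A_COMPATIBLE) else off + 1L
      pat <- Biostrings::DNAString(pattern)
      for (str in c("+", "-")) {
        qp <- if (str == "+") pat else Biostrings::reverseComplement(pat)
        hits <- Biostrings::matchPattern(qp, chromSeq, fixed = "subject")
        if (length(hits) == 0) next
        s <- BiocGenerics::start(hits)
        e <- BiocGenerics::end(hits)
        # a reference N never matches, not even a pattern N
        noN <- !grepl("N", substring(chromStr, s, e), fixed = TRUE)
        s <- s[noN]
        e <- e[noN]
        if (length(s) == 0) next
        # map pattern index j to a forward-strand coordinate and require the
        # strand-specific base there to be adenine
        adenine <- lapply(seq_along(s), function(i) {
          coords <- if (str == "+") s[i] + candIdx - 1L else e[i] - candIdx + 1L
          base <- substring(chromStr, coords, coords)
          want <- if (str == "+") "A" else "T"
          sort(coords[base == want])
        })
        gr <- GenomicRanges::GRanges(
          seqnames = chrom,
          ranges = IRanges::IRanges(start = s, end = e),
          strand = str
        )
        gr$motif <- motifs@name[mi]
        gr$adeninePositions <- IRanges::IntegerList(adenine)
        out[[length(out) + 1L]] <- gr
      }
    }
  }
  if (length(out) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$motif <- character()
    gr$adeninePositions <- IRanges::IntegerList()
    return(gr)
  }
  res <- suppressWarnings(do.call(c, out))
  res[order(match(as.character(GenomicRanges::seqnames(res)), names(genome)),
            GenomicRanges::start(res),
            as.character(GenomicRanges::strand(res)))]
}

#' Classify calls as motif or non-motif
#'
#' A call is "on motif" iff its (chromosome, position, strand) coincides
#' with a candidate methylated-adenine coordinate of an occurrence on the
#' same strand. A call hit by several motifs receives all their names;
#' such a call still counts once in the total-motif count M.
#'
#' @param calls call `GRanges`.
#' @param occurrences occurrence `GRanges` from [scanMotifs()].
#' @return a `CharacterList` parallel to `calls`: the motif names covering
#'   each call (empty = non-motif).
#' @export
classifyCalls <- function(calls, occurrences) {
  if (length(calls) == 0) return(IRanges::CharacterList())
  if (length(occurrences) == 0)
    return(IRanges::CharacterList(rep(list(character(0)), length(calls))))
  ap <- occurrences$adeninePositions
  nper <- lengths(ap)
  adf <- data.frame(
    key = paste(rep(as.character(GenomicRanges::seqnames(occurrences)), nper),
                unlist(ap),
                rep(as.character(GenomicRanges::strand(occurrences)), nper),
                sep = "\r"),
    motif = rep(occurrences$motif, nper),
    stringsAsFactors = FALSE
  )
  adf <- unique(adf)
  lookup <- split(adf$motif, adf$key)
  callKey <- paste(as.character(GenomicRanges::seqnames(calls)),
                   GenomicRanges::start(calls),
                   as.character(GenomicRanges::strand(calls)),
                   sep = "\r")
  hits <- lookup[callKey]
  hits[vapply(hits, is.null, logical(1))] <- list(character(0))
  IRanges::CharacterList(unname(hits))
}

#' Per-motif and total-motif proportions across analysis states
#'
#' For each analysis state (e.g. the raw SMRT call set, calls inside MeDIP
#' peaks, calls above the IPD threshold, and both) computes, per motif, the
#' proportion m/N of state calls carrying that motif, and in total the
#' proportion M/N of state calls on any motif. Undefined ratios (N = 0) are
#' reported as `NA`, never as 0. When both a before state and a thresholded
#' state are identified, the total-motif increase I and non-motif decrease
#' D between them are computed (see [increaseDecrease()]).
#'
#' @param stateLabels named list, one element per state, each a
#'   `CharacterList` (or list of character vectors) of per-call motif
#'   labels as returned by [classifyCalls()]. Every state should be a
#'   subset of the first (baseline) state.
#' @param motifNames motifs to tabulate; defaults to all labels observed.
#' @param beforeState,afterState state names used for I and D; default the
#'   first state and, when present, the state named "PacBio+threshold"
#'   (otherwise the last state).
#' @return a [MotifProportionReport-class].
#' @export
computeStateProportions <- function(stateLabels, motifNames = NULL,
                                    beforeState = names(stateLabels)[1],
                                    afterState = NULL) {
  if (is.null(names(stateLabels)) || any(!nzchar(names(stateLabels))))
    stop("stateLabels must be a named list of per-state label sets")
  stateLabels <- lapply(stateLabels, as.list)
  if (length(stateLabels[[beforeState]]) == 0)
    stop("the baseline state '", beforeState, "' is empty")
  if (is.null(motifNames))
    motifNames <- sort(unique(unlist(stateLabels, use.names = FALSE)))
  if (is.null(afterState)) {
    afterState <- if ("PacBio+threshold" %in% names(stateLabels))
      "PacBio+threshold" else names(stateLabels)[length(stateLabels)]
  }
  counts <- function(labels) {
    N <- length(labels)
    M <- sum(lengths(labels) > 0)
    m <- vapply(motifNames,
                function(mo) sum(vapply(labels, function(l) mo %in% l,
                                        logical(1))),
                integer(1))
    list(N = N, M = M, m = m)
  }
  st <- lapply(stateLabels, counts)
  perMotif <- do.call(rbind, lapply(names(st), function(sn) {
    c0 <- st[[sn]]
    data.frame(motif = motifNames, state = sn,
               m = unname(c0$m), N = c0$N,
               proportion = if (c0$N > 0) unname(c0$m) / c0$N else NA_real_,
               stringsAsFactors = FALSE)
  }))
  totals <- do.call(rbind, lapply(names(st), function(sn) {
    c0 <- st[[sn]]
    data.frame(state = sn, M = c0$M, N = c0$N,
               proportion = if (c0$N > 0) c0$M / c0$N else NA_real_,
               stringsAsFactors = FALSE)
  }))
  I <- NA_real_
  D <- NA_real_
  if (beforeState %in% names(st) && afterState %in% names(st) &&
      !identical(beforeState, afterState)) {
    b <- st[[beforeState]]
    a <- st[[afterState]]
    id <- increaseDecrease(N = b$N, M = b$M, Nthr = a$N, Mthr = a$M)
    I <- id$I
    D <- id$D
  }
  new("MotifProportionReport", perMotif = perMotif, totals = totals,
      increase = I, decrease = D)
}

#' Total-motif increase and non-motif decrease statistics
#'
#' Given the total call count N and motif-call count M before thresholding
#' and their counterparts after thresholding, computes
#' \deqn{I = M_{thr}/N_{thr} - M/N,}
#' the increase in the total-motif proportion, and
#' \deqn{D = (1 - M/N) - (N_{thr} - M_{thr})/N,}
#' the decrease in the non-motif proportion. Note that D times N equals the
#' number of non-motif calls removed by the threshold. I is undefined
#' (`NA`) when the thresholded set is empty.
#'
#' @param N,M total and motif-call counts before thresholding (N > 0).
#' @param Nthr,Mthr the same counts after thresholding (subset of the
#'   before state: Nthr <= N, Mthr <= M, Mthr <= Nthr).
#' @return list with elements `I` and `D`.
#' @examples
#' increaseDecrease(N = 10, M = 6, Nthr = 5, Mthr = 4)  # I = 0.2, D = 0.3
#' @export
increaseDecrease <- function(N, M, Nthr, Mthr) {
  if (N <= 0) stop("N must be positive")
  if (Nthr > N || Mthr > M || Mthr > Nthr || M > N)
    stop("thresholded counts must be a subset: need Nthr <= N, Mthr <= min(M, Nthr), M <= N")
  I <- if (Nthr > 0) Mthr / Nthr - M / N else NA_real_
  D <- (1 - M / N) - (Nthr - Mthr) / N
  list(I = I, D = D)
}

#' Motif composition of threshold-removed calls
#'
#' Among the calls removed by the IPD-ratio threshold, the proportions
#' that are on a motif versus not; a high non-motif share among removed
#' calls supports the removed calls being false positives.
#'
#' @param removedLabels `CharacterList` (or list) of motif labels for the
#'   removed calls, from [classifyCalls()].
#' @return named numeric `c(motif =, nonMotif =)` summing to 1, or both
#'   `NA` when nothing was removed.
#' @export
filteredComposition <- function(removedLabels) {
  removedLabels <- as.list(removedLabels)
  n <- length(removedLabels)
  if (n == 0) return(c(motif = NA_real_, nonMotif = NA_real_))
  onMotif <- sum(lengths(removedLabels) > 0)
  c(motif = onMotif / n, nonMotif = (n - onMotif) / n)
}
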