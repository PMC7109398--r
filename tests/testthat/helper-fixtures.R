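# fixtures and independent oracles shared across test files; all fixtures
# are built in code at test time

# peak GRanges builder taking BED-style 0-based half-open coordinates
makePeaks <- function(chrom, start0, end0, enrichment = 5,
                      negLog10Q = 10, negLog10P = NULL, name = NULL) {
  n <- length(start0)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    strand = "*"
  )
  gr$name <- if (is.null(name)) paste0("p", seq_len(n)) else name
  gr$displayScore <- 0
  gr$enrichment <- rep_len(enrichment, n)
  gr$negLog10P <- if (is.null(negLog10P)) rep_len(negLog10Q + 1, n) else
    rep_len(negLog10P, n)
  gr$negLog10Q <- rep_len(negLog10Q, n)
  gr$summitOffset <- rep_len(-1L, n)
  gr
}

# random call table over a set of chromosomes
randomCalls <- function(n, seed, chroms = c("chr1", "chr2"), maxPos = 10000L) {
  set.seed(seed)
  modCalls(
    chrom = sample(chroms, n, replace = TRUE),
    position = sample.int(maxPos, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    ipdRatio = round(stats::runif(n, 0.5, 8), 3),
    coverage = sample(10:200, n, replace = TRUE),
    score = sample(0:60, n, replace = TRUE),
    fraction = ifelse(stats::runif(n) < 0.1, NA_real_,
                      round(stats::runif(n), 3))
  )
}

# independent IUPAC scanner oracle: degenerate pattern -> regex character
# classes, overlapping matches via lookahead, minus strand via the reverse
# complement of the pattern on the forward sequence
iupacRegex <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  paste(vapply(strsplit(pattern, "")[[1]],
               function(ch) paste0("[", sets[[ch]], "]"), character(1)),
        collapse = "")
}

revcompStr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# all overlapping match start positions (1-based) of a degenerate pattern
regexStarts <- function(pattern, sequence) {
  rx <- paste0("(?=", iupacRegex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# oracle occurrence table for one chromosome: data.frame(start, strand)
oracleScan <- function(pattern, sequence) {
  plus <- regexStarts(pattern, sequence)
  minus <- regexStarts(revcompStr(pattern), sequence)
  rbind(
    if (length(plus)) data.frame(start = plus, strand = "+") else NULL,
    if (length(minus)) data.frame(start = minus, strand = "-") else NULL
  )
}

randomSeq <- function(len, seed, gc = 0.5, nN = 0) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(p), len, replace = TRUE, prob = p)
  if (nN > 0) s[sample.int(len, nN)] <- "N"
  paste(s, collapse = "")
}

# small conservative set built through the public API with permissive
# cutoffs and one covering peak
conservativeFromIpd <- function(ipd, chrom = "chr1") {
  n <- length(ipd)
  calls <- modCalls(chrom, seq_len(n) + 10L, "+", ipd,
                    coverage = 100L, score = 40, fraction = 0.9)
  peak <- makePeaks(chrom, 0, n + 100L)
  buildConservativeSet(calls, peak)
}
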