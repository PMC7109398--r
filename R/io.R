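#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString alphabetFrequency
#' @importFrom utils read.csv write.table
NULL

#' Read a reference genome from FASTA
#'
#' Loads a (multi-)FASTA file into a `DNAStringSet`. Sequence names are
#' truncated at the first whitespace, sequences are uppercased, and only
#' the A/C/G/T/N alphabet is accepted.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(names(seqs)))) stop("empty sequence identifier in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifier(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  af <- Biostrings::alphabetFrequency(seqs)
  extra <- colSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
  if (sum(extra) > 0)
    stop("genome contains characters outside A/C/G/T/N: ",
         paste(names(extra)[extra > 0], collapse = ", "))
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read MACS2 narrowPeak files
#'
#' Parses the 10-column BED6+4 narrowPeak format positionally (never by
#' header): columns 7, 8 and 9 are the fold enrichment, -log10(p) and
#' -log10(q) of each peak. BED half-open 0-based intervals are converted
#' to the 1-based closed `GRanges` convention, so a BED peak `[100, 150)`
#' becomes the range 101-150.
#'
#' @param path path to a narrowPeak file; `track` and `#` lines are skipped.
#' @return a `GRanges` with metadata columns name, displayScore,
#'   enrichment, negLog10P, negLog10Q, summitOffset.
#' @seealso [filterPeaks()], [writeNarrowPeak()]
#' @export
readNarrowPeak <- function(path) {
  if (!file.exists(path)) stop("narrowPeak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(emptyPeaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    stop(sprintf("narrowPeak line %d: expected 10 tab-separated columns, got %d",
                 lineno[bad], nf[bad]))
  }
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("narrowPeak line %d: non-numeric %s '%s'",
                   lineno[bad], what, m[bad, col]))
    }
    v
  }
  start0 <- num(2, "start")
  end0 <- num(3, "end")
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1]
    stop(sprintf("narrowPeak line %d: start (%s) >= end (%s)",
                 lineno[bad], m[bad, 2], m[bad, 3]))
  }
  strand <- m[, 6]
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    strand = strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = m[, 4],
    displayScore = num(5, "score"),
    enrichment = num(7, "signalValue"),
    negLog10P = num(8, "pValue"),
    negLog10Q = num(9, "qValue"),
    summitOffset = as.integer(num(10, "peak offset"))
  )
  if (any(gr$enrichment < 0) || any(gr$negLog10Q < 0))
    stop("narrowPeak enrichment and -log10(q) must be non-negative")
  gr
}

emptyPeaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(), displayScore = numeric(), enrichment = numeric(),
    negLog10P = numeric(), negLog10Q = numeric(), summitOffset = integer()
  )
  gr
}

#' Write peaks as narrowPeak
#'
#' Inverse of [readNarrowPeak()]: emits valid 10-column narrowPeak with
#' BED 0-based half-open coordinates.
#'
#' @param peaks a peak `GRanges` as returned by [readNarrowPeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = peaks$name,
    score = peaks$displayScore,
    strand = strand,
    signalValue = numFmt(peaks$enrichment),
    pValue = numFmt(peaks$negLog10P),
    qValue = numFmt(peaks$negLog10Q),
    peak = peaks$summitOffset
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# full-precision, round-trippable decimal text for doubles
numFmt <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    s
  }, character(1))
}

#' Read SMRT base-modification calls (GFF dialect)
#'
#' Reads the GFF3 dialect written by the PacBio modification-detection step:
#' the feature type is the modification label (e.g. `m6A` or
#' `modified_base`), both coordinate columns hold the same 1-based position
#' of the modified base, the score column is the modification QV, and the
#' attribute field carries `coverage`, `IPDRatio` and optionally `frac`.
#'
#' @param path path to a modifications GFF file.
#' @param modType keep only records of this modification type (default
#'   "m6A"); `NULL` keeps every record.
#' @return a call `GRanges` (see [modCalls()]); unknown GFF attributes are
#'   preserved as extra character metadata columns so that writing does not
#'   discard upstream metadata.
#' @seealso [writeCalls()], [readModificationsCsv()]
#' @export
readModificationsGff <- function(path, modType = "m6A") {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      modType = character(), ipdRatio = numeric(), coverage = integer(),
      score = numeric(), fraction = numeric())
    return(out)
  }
  mc <- S4Vectors::mcols(gr)
  if (!is.null(modType)) {
    keep <- as.character(mc$type) == modType
    gr <- gr[keep]
    mc <- mc[keep, , drop = FALSE]
  }
  for (required in c("IPDRatio", "coverage")) {
    if (!required %in% names(mc))
      stop("GFF records lack the '", required, "' attribute: ", path)
    v <- suppressWarnings(as.numeric(as.character(mc[[required]])))
    if (anyNA(v))
      stop(sprintf("record %d of %s: missing or unparsable '%s' attribute",
                   which(is.na(v))[1], path, required))
    mc[[required]] <- v
  }
  fraction <- rep(NA_real_, length(gr))
  if ("frac" %in% names(mc)) {
    fr <- as.character(mc$frac)
    has <- !is.na(fr) & nzchar(fr)
    fraction[has] <- suppressWarnings(as.numeric(fr[has]))
    if (anyNA(fraction[has]))
      stop("unparsable 'frac' attribute in ", path)
  }
  score <- as.numeric(mc$score)
  if (anyNA(score)) stop("missing score (modification QV) in ", path)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = GenomicRanges::start(gr), width = 1L),
    strand = GenomicRanges::strand(gr)
  )
  extras <- setdiff(names(mc),
                    c("source", "type", "score", "phase", "IPDRatio",
                      "coverage", "frac", "ID", "identificationQv"))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    modType = as.character(mc$type),
    ipdRatio = mc$IPDRatio,
    coverage = as.integer(mc$coverage),
    score = score,
    fraction = fraction
  )
  for (e in extras) S4Vectors::mcols(out)[[e]] <- as.character(mc[[e]])
  msgs <- validateCallRanges(out)
  if (length(msgs)) stop("invalid calls in ", path, ": ",
                         paste(msgs, collapse = "; "))
  out
}

#' Read SMRT base-modification calls (flat CSV dialect)
#'
#' Reads the per-site CSV table written by the same upstream caller:
#' mandatory columns `tpl` (1-based template position), `strand` (0 for the
#' forward, 1 for the reverse strand), `score`, `ipdRatio` and `coverage`;
#' optional `frac` and `base`. When a `base` column is present only
#' adenine rows are kept for 6mA analysis.
#'
#' @param path path to the CSV file.
#' @param chrom chromosome identifier to assign when the file has no
#'   refName column (single-reference runs), default "ref".
#' @return a call `GRanges` (see [modCalls()]).
#' @export
readModificationsCsv <- function(path, chrom = "ref") {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("tpl", "strand", "score", "ipdRatio", "coverage")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("CSV is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if ("base" %in% names(df)) df <- df[toupper(df$base) == "A", , drop = FALSE]
  if ("refName" %in% names(df)) chrom <- gsub('"', "", df$refName)
  strand <- ifelse(df$strand == 0, "+", "-")
  fraction <- if ("frac" %in% names(df)) as.numeric(df$frac) else NA_real_
  modCalls(chrom = chrom, position = df$tpl, strand = strand,
           ipdRatio = df$ipdRatio, coverage = df$coverage,
           score = df$score, fraction = fraction)
}

#' Read a motif list
#'
#' Tab-separated, no header: motif name, IUPAC pattern, and an optional
#' third column giving the 0-based offset of the methylated adenine in the
#' pattern (an integer, or "any" — the default — meaning every
#' A-compatible pattern position).
#'
#' @param path path to the motif TSV.
#' @return a [MotifSet-class].
#' @export
readMotifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) stop("empty motif file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2))
    stop("motif line with fewer than 2 tab-separated fields in ", path)
  name <- vapply(fields, `[`, character(1), 1)
  pattern <- vapply(fields, `[`, character(1), 2)
  off <- vapply(fields, function(f) if (length(f) >= 3) f[3] else "any",
                character(1))
  offInt <- ifelse(tolower(off) == "any", NA_integer_,
                   suppressWarnings(as.integer(off)))
  if (any(tolower(off) != "any" & is.na(offInt)))
    stop("methylated offset must be an integer or 'any' in ", path)
  MotifSet(name = name, pattern = pattern, methylatedOffset = offInt)
}

#' Write a motif list
#'
#' @param motifs a [MotifSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifs <- function(motifs, path) {
  off <- ifelse(is.na(motifs@methylatedOffset), "any",
                as.character(motifs@methylatedOffset))
  writeLines(paste(motifs@name, motifs@pattern, off, sep = "\t"), path)
  invisible(path)
}

#' Write modification calls to GFF or BED
#'
#' GFF output uses the same dialect [readModificationsGff()] reads and
#' round-trips all modeled fields (position, strand, type, QV score,
#' coverage, IPD ratio, fraction, plus any preserved extra attributes).
#' BED output is 0-based half-open single-base intervals with strand; the
#' BED score column carries the modification QV.
#'
#' @param calls a call `GRanges`.
#' @param path output path.
#' @param format "gff" or "bed".
#' @return `path`, invisibly.
#' @export
writeCalls <- function(calls, path, format = c("gff", "bed")) {
  format <- match.arg(format)
  msgs <- validateCallRanges(calls)
  if (length(msgs)) stop("invalid calls: ", paste(msgs, collapse = "; "))
  if (format == "bed") {
    if (length(calls) == 0) {
      writeLines(character(), path)
      return(invisible(path))
    }
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(calls)),
      start = GenomicRanges::start(calls) - 1L,
      end = GenomicRanges::start(calls),
      name = calls$modType,
      score = numFmt(calls$score),
      strand = as.character(GenomicRanges::strand(calls))
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  header <- "##gff-version 3"
  if (length(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(calls)
  extras <- setdiff(names(mc), CALL_MCOLS)
  attrs <- paste0("coverage=", calls$coverage)
  for (e in extras) {
    v <- as.character(mc[[e]])
    has <- !is.na(v) & nzchar(v)
    attrs[has] <- paste0(attrs[has], ";", e, "=", v[has])
  }
  attrs <- paste0(attrs, ";IPDRatio=", numFmt(calls$ipdRatio))
  hasFrac <- !is.na(calls$fraction)
  attrs[hasFrac] <- paste0(attrs[hasFrac], ";frac=",
                           numFmt(calls$fraction[hasFrac]))
  lines <- paste(
    as.character(GenomicRanges::seqnames(calls)),
    "kinModCall",
    calls$modType,
    GenomicRanges::start(calls),
    GenomicRanges::start(calls),
    numFmt(calls$score),
    as.character(GenomicRanges::strand(calls)),
    ".",
    attrs,
    sep = "\t"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}
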