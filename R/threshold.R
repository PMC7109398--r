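#' @importFrom stats qt sd shapiro.test
NULL

#' Sample IPD ratios from the conservative set
#'
#' Draws a simple random sample (without replacement by default) of IPD
#' ratios from the conservative set. The draw is deterministic given the
#' seed; the caller's RNG state is left untouched.
#'
#' @param conservative a [ConservativeSet-class].
#' @param n sample size (default 30).
#' @param seed integer RNG seed (required for reproducibility).
#' @param replace sample with replacement (default `FALSE`).
#' @return numeric vector of `n` IPD ratios.
#' @export
sampleIpdRatios <- function(conservative, n = 30, seed, replace = FALSE) {
  stopifnot(is(conservative, "ConservativeSet"))
  n <- as.integer(n)
  if (n < 2) stop("sample size n must be >= 2")
  pool <- conservativeCalls(conservative)$ipdRatio
  if (!replace && length(pool) < n)
    stop(sprintf(paste0(
      "conservative set has %d call(s), fewer than the requested sample ",
      "size n = %d; relax the strict cutoffs or lower n"),
      length(pool), n))
  if (missing(seed) || is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("no seed supplied; drew seed ", seed)
  }
  if (!replace && length(pool) == n) return(pool)
  withSeed(seed, sample(pool, n, replace = replace))
}

#' Derive the IPD-ratio threshold from a sample
#'
#' Computes the lower bound of the two-sided confidence interval for the
#' population mean IPD ratio,
#' \deqn{\mathrm{threshold} = \bar{X} - c \, S/\sqrt{n},}
#' where \eqn{S} uses the n-1 denominator. In `"normal"` mode the critical
#' multiplier c is the rounded normal quantile 1.96 traditionally quoted
#' for alpha = 0.05 (and used by the original procedure); `"student"` mode
#' uses the exact quantile \eqn{t_{\alpha/2}(n-1)} (2.045 for n = 30); a
#' numeric `critical` is used as-is. A constant sample (S = 0) is allowed and yields threshold equal to
#' the sample mean.
#'
#' @param sample numeric vector of sampled IPD ratios (length >= 2, all
#'   positive).
#' @param alpha significance level (default 0.05).
#' @param critical `"normal"` (the rounded normal quantile 1.96, as in the
#'   original procedure), `"student"` (the exact Student quantile) or a
#'   numeric multiplier.
#' @param seed optional integer recorded as the seed that produced
#'   `sample`.
#' @return a [ThresholdModel-class].
#' @examples
#' computeThreshold(3 + 0.1 * (1:30))
#' @export
computeThreshold <- function(sample, alpha = 0.05, critical = "normal",
                             seed = NULL) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 2) stop("need a sample of size >= 2")
  if (any(!is.finite(sample)) || any(sample <= 0))
    stop("IPD ratios must be finite and positive")
  if (is.numeric(critical)) {
    crit <- critical
    mode <- "fixed"
  } else {
    mode <- match.arg(critical, c("normal", "student"))
    crit <- if (mode == "normal") 1.96 else stats::qt(1 - alpha / 2, df = n - 1)
  }
  m <- mean(sample)
  s <- stats::sd(sample)
  new("ThresholdModel",
      sampleValues = sample, n = as.integer(n), alpha = alpha,
      criticalValue = crit, mode = mode, sampleMean = m, sampleSD = s,
      threshold = m - crit * s / sqrt(n),
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Apply an IPD-ratio threshold to a call set
#'
#' Partitions calls into retained (`ipdRatio >= threshold`, inclusive) and
#' removed (`ipdRatio < threshold`), preserving input order in both parts.
#' The retained set is the quality-controlled 6mA set.
#'
#' @param calls call `GRanges`.
#' @param threshold finite numeric threshold, or a [ThresholdModel-class].
#' @return a [FilterResult-class].
#' @export
applyThreshold <- function(calls, threshold) {
  if (is(threshold, "ThresholdModel")) threshold <- thresholdValue(threshold)
  if (!is.finite(threshold)) stop("threshold must be finite")
  keep <- calls$ipdRatio >= threshold
  new("FilterResult", thresholdUsed = threshold,
      retained = calls[keep], removed = calls[!keep],
      nInput = length(calls))
}

#' Threshold stability across repeated samplings
#'
#' Repeats the sample-and-threshold step `k` times with independent seeds
#' and summarises the dispersion of the derived thresholds, mirroring the
#' replicate stability check of the method (small deviations across
#' repeated samplings indicate the threshold is robust to sampling bias).
#'
#' @param conservative a [ConservativeSet-class].
#' @param k number of replicates (>= 2).
#' @param n sample size per replicate (default 30).
#' @param seeds integer vector of length `k`.
#' @param alpha,critical passed to [computeThreshold()].
#' @return a list with `models` (list of [ThresholdModel-class]),
#'   `thresholds` (numeric vector) and `summary` (min, max, mean, sd,
#'   maxPairwiseDiff).
#' @export
replicateThresholds <- function(conservative, k = 3, n = 30, seeds,
                                alpha = 0.05, critical = "normal") {
  if (k < 2) stop("k must be >= 2")
  if (length(seeds) != k) stop("need exactly k seeds")
  models <- lapply(seq_len(k), function(i) {
    s <- sampleIpdRatios(conservative, n = n, seed = seeds[i])
    computeThreshold(s, alpha = alpha, critical = critical, seed = seeds[i])
  })
  thr <- vapply(models, thresholdValue, numeric(1))
  list(
    models = models,
    thresholds = thr,
    summary = c(min = min(thr), max = max(thr), mean = mean(thr),
                sd = stats::sd(thr), maxPairwiseDiff = max(thr) - min(thr))
  )
}

#' Advisory normality check of the IPD-ratio sample
#'
#' The threshold rests on a normal model for the conservative set's IPD
#' ratios; this runs a Shapiro-Wilk test on the sample as a diagnostic. It
#' never blocks the pipeline: a warning is emitted when p < 0.05, and a
#' constant sample is flagged non-testable.
#'
#' @param sample numeric vector (length >= 3).
#' @return a list with `testable` (logical), `statistic`, `p.value` and
#'   `method`.
#' @export
checkSampleNormality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 3) stop("need at least 3 values for a normality test")
  if (stats::sd(sample) == 0) {
    warning("constant sample: normality is not testable")
    return(list(testable = FALSE, statistic = NA_real_, p.value = NA_real_,
                method = "Shapiro-Wilk"))
  }
  ht <- stats::shapiro.test(sample)
  if (ht$p.value < 0.05)
    warning(sprintf(
      "sample departs from normality (Shapiro-Wilk p = %.3g); the confidence-interval threshold may be unreliable",
      ht$p.value))
  list(testable = TRUE, statistic = unname(ht$statistic),
       p.value = ht$p.value, method = "Shapiro-Wilk")
}
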