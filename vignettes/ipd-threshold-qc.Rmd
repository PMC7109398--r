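---
title: "MeDIP-guided IPD-ratio thresholding of SMRT 6mA calls: methods and design"
author: "sixmaQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MeDIP-guided IPD-ratio thresholding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmaQC)
```

## The problem

SMRT sequencing detects base modifications from polymerase kinetics: at a
modified template position the inter-pulse duration (IPD) is elevated, and
the modification caller reports, per position and strand, an IPD ratio
(observed over expected IPD), a read `coverage`, a Phred-type modification
QV (`score` = -10 log10 p), and an estimated methylated read `fraction`.
For N6-methyladenine (6mA) this works well in bacteria, where 6mA is
abundant and sits almost entirely (> 95%) on short
restriction–modification motifs such as GATC. In eukaryotes 6mA is rare
and only weakly motif driven (a few percent of calls on motifs), so the
kinetic signal of true sites is swamped by false positives from DNA
damage, 5mC and its demethylation intermediates, and plain noise. The
usual remedy — sequencing whole-genome-amplified (WGA, unmethylated) DNA
as a kinetics baseline — doubles the sequencing cost.

This package implements the alternative: use MeDIP-seq (antibody
enrichment of methylated DNA, peaks called with MACS2) as the control.
MeDIP peaks cannot resolve single bases, but they mark regions where
methylation is real. Calls that both look excellent kinetically *and* fall
inside a confident peak are very likely true; their IPD ratios calibrate a
genome-wide filter.

## The procedure

1. **Basic pass.** Genome-wide calls are floored at `coverage >= 50`
   (per-site; a per-chromosome-mean variant is available via
   `perChromosomeCoverage = TRUE`). This is the "PacBio" state, the set N.
2. **Conservative set.** Peaks are filtered at fold `enrichment >= 1` and
   `-log10(q) >= 2` (q <= 0.01, as MACS2 writes the qValue column); calls
   at `coverage >= 50`, `score >= 30` (p <= 0.001) and `fraction >= 0.7`.
   All comparisons are inclusive. Filtered calls inside filtered peaks
   form the conservative set (`buildConservativeSet()`).
3. **Threshold.** The conservative set's IPD ratios are modeled as
   normal. A simple random sample of n = 30 (without replacement) gives
   the two-sided confidence interval for the mean at alpha = 0.05, and the
   *lower bound* is the threshold:
   \[
   \mathrm{thres} = \bar{X} - t_{\alpha/2}(n-1)\,\frac{S}{\sqrt{n}} .
   \]
   `checkSampleNormality()` runs a Shapiro–Wilk diagnostic on the sample;
   it warns but never blocks.
4. **Filter.** Every call with `ipdRatio >= thres` (inclusive) is
   retained; the rest are removed as putative false positives
   (`applyThreshold()`).
5. **Evaluation.** Calls are classified against IUPAC motif occurrences on
   both strands. For each motif, the proportion m/N of calls on that motif
   is tabulated in four states — PacBio, PacBio+MeDIP, PacBio+threshold,
   PacBio+MeDIP+threshold — together with the total-motif proportion M/N,
   the increase `I = M_thr/N_thr - M/N` and the non-motif decrease
   `D = (1 - M/N) - (N_thr - M_thr)/N`. D·N equals the count of non-motif
   calls removed, an identity the tests verify exactly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `basicMinCoverage` | 50x | depth floor for any call to be considered |
| `minCoverage, minScore, minFraction` | 50, 30, 0.7 | strict call cutoffs for the conservative set |
| `minEnrichment, minNegLog10Q` | 1, 2 | strict peak cutoffs (q <= 0.01) |
| `n` | 30 | IPD-ratio sample size |
| `alpha` | 0.05 | confidence level of the interval |
| `critical` | `"normal"` | multiplier mode, see below |
| `seed` | — | mandatory for the sample draw |

**The critical multiplier.** The multiplier conventionally quoted for
alpha = 0.05, n = 30 is 1.96 — the *normal* quantile, although the exact
Student quantile t_{0.025}(29) is 2.045. `critical = "normal"` (the
default, matching the original procedure) uses 1.96; `"student"` computes
the exact quantile (a slightly lower, more permissive threshold); a
numeric value is used as-is. The mode is recorded in the run provenance.

**Sampling.** A single draw of n = 30 per threshold, without replacement
(`replace = TRUE` is available). If the conservative set is smaller than
n, the package stops with advice to relax cutoffs or lower n — it never
silently falls back. `replicateThresholds()` repeats the draw with
independent seeds and reports the dispersion; because the sampling error
of the mean is S/sqrt(30), replicate thresholds on a homogeneous
conservative set typically differ by well under 0.2.

## Coordinate and counting conventions

- Calls are width-1 `GRanges` (1-based, GFF-native); narrowPeak intervals
  are converted from BED 0-based half-open to 1-based closed on read and
  back on write. A call at 1-based position p is inside BED peak [s, e)
  iff s <= p-1 < e; a call exactly at the BED end coordinate is outside.
- narrowPeak parsing is positional (columns 7/8/9 = enrichment,
  -log10 p, -log10 q), never header-based.
- Duplicate calls (same chromosome, position, strand) are collapsed with
  a warning before any counting, since they would double-count in the
  proportion statistics.
- Motif matching uses IUPAC semantics for the pattern; an N in the
  *reference* never matches anything, not even a pattern N. Minus-strand
  occurrences are found as reverse-complement matches on the forward
  sequence. A call is "on motif" iff its position and strand coincide
  with an A-compatible motif position whose reference base is adenine on
  that strand ("any" policy); a motif's `methylatedOffset` narrows this
  to one pattern position. A call on several motifs counts once in M and
  once per motif in m, keeping M <= N.
- Undefined ratios (empty states, 0/0) are reported as `NA`, never
  coerced to 0.

## The synthetic-data generator

Real datasets behind this method are multi-gigabyte SRA downloads, so the
package ships a generator (`simulationConfig()`, `simulateDataset()`) that
emulates the two regimes the method must span, with full ground truth:

- **prokaryote-like**: GATC and GANTC motifs; 95% of motif adenines
  methylated; 170 off-motif true sites so that ~95% of true calls sit on
  motifs; 1,500 false calls.
- **eukaryote-like**: the degenerate motif VATB; a tiny fraction (0.0015)
  of motif adenines methylated plus 1,200 off-motif true sites, putting
  ~2% of true calls on motifs; 4,000 false calls, so false positives
  dominate as they do in low-abundance genomes.

Both use a 200 kb i.i.d. genome at GC 0.5 (a scale at which the pipeline
and its tests run in seconds while every count is in the thousands), true
IPD ~ N(5.0, 0.5²) and false IPD ~ N(1.8, 0.4²) truncated positive — a
well-separated mixture, ~7 sigma between means — coverage ~ negative
binomial (mu 100, size 10) floored at 10x, methylated fractions
Beta(12, 3) for true calls (most mass above 0.7) and Beta(2.5, 2.5) for
false ones, and a modification QV that grows monotonically with IPD
elevation and depth, clipped to 1–60. Motif copies are planted by
overwriting the sequence at non-overlapping loci so configured counts are
guaranteed; the final genome is then re-scanned so natural background
occurrences join the ground truth and are never mislabeled. False calls
are placed only at non-motif adenines. MeDIP peaks of width 500 are laid
over clusters of true sites (90%/80% coverage by regime), with decoy
peaks that almost always fail the strict filter. Everything is
deterministic per seed, down to byte-identical files.

What the generator does *not* emulate: skewed or heavy-tailed empirical
IPD distributions, kinetic crosstalk from neighboring modifications,
coverage-dependent IPD-ratio variance, fragment-level MeDIP enrichment
biases, and natural motif composition of real genomes. Passing tests on
this generator therefore demonstrate correctness of the computations and
the qualitative behaviour of the method, not its real-data error rates.

```{r example, eval = FALSE}
cfg <- simulationConfig("prokaryote", seed = 11)
sim <- simulateDataset(cfg)
run <- runQC(sim$calls, sim$peaks, sim$genome, cfg$motifs, seed = 11)
run
evaluateRun(run, sim$truth)
```

## Design choices where the design was open

- **Peak strand is ignored** during intersection: MeDIP peaks are
  unstranded; call strand is kept and used for motif matching.
- **"Coverage per chromosome"** is read as a per-site depth cutoff (it is
  the site-level feature the caller reports); the chromosome-mean reading
  is available behind `perChromosomeCoverage`.
- **The q-value transform** is -log10, not -10·log10: only -log10
  reproduces the printed anchor pairs (1.3 for q = 0.05, 2 for q = 0.01),
  so the numbers are followed rather than the notation. Likewise the
  modification score is the Phred QV -10·log10(p) (20 for 0.01, 30 for
  0.001).
- **The threshold is applied genome-wide** to the basic-filtered call
  set, not only to peak-overlapping calls, so that the "threshold only"
  and "MeDIP + threshold" states remain distinct and comparable.
- **Replicate stability** resamples the same conservative set with fresh
  seeds; upstream steps are not re-run.

## Known limitations

- The threshold is the lower confidence bound of the conservative set's
  *mean*. Since the conservative set is dominated by true sites, the
  threshold lands near the true-component mean, roughly the upper half of
  the true IPD distribution. The filter is therefore deliberately
  conservative: precision and specificity are near 1 on well-separated
  synthetic mixtures (the tests compute both), while roughly half of the
  weaker true sites fall below the threshold and are sacrificed. Users
  who need recall over purity should lower the critical multiplier or
  use an externally calibrated threshold (`threshold =` in `runQC()`).
- A single draw of n = 30 keeps fidelity to the published procedure but
  makes the threshold itself a random variable with sd about S/sqrt(30);
  `replicateThresholds()` quantifies this.
- The normal model for conservative-set IPD ratios is asserted, not
  estimated; the Shapiro–Wilk diagnostic warns when it is implausible.
- Chromosomes are filtered jointly; per-chromosome thresholds are out of
  scope, as are mixture-model or empirical-Bayes alternatives.
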