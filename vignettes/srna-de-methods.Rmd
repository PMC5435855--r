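---
title: "Methods: small RNA QC, normalization and CI/LOFC differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA QC, normalization and CI/LOFC differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnadekit)
```

# Scope and data model

`srnadekit` analyses bulk sRNA-seq count data at single-sequence
resolution: a *read library* maps each unique 15–35 nt sequence of one
replicate to its abundance, and an *expression matrix* stacks libraries
over an ordered treatment/replicate hierarchy. The ordering matters —
the differential expression caller compares consecutive treatments by
default, which is the natural reading of a time series; a
`vs_reference` scheme covers wild-type-versus-treatments designs.

Alignment is exact, full length, ungapped, on both strands, reporting
all occurrences. In the 18–30 nt regime a single mismatch changes the
identity of the small RNA, and mismatch tolerance would blur the
strand-bias signal the offset estimator depends on, so none is offered.
Internally all coordinates are 0-based half-open; SAM (1-based) and
GFF3 (1-based inclusive) are converted at the I/O boundary only. A
minus-strand hit at start $s$ means the read equals the reverse
complement of the genome slice $[s, s + \ell)$.

Annotation classification uses full containment: a read belongs to
class $C$ if at least one hit lies entirely inside a feature of type
$C$, strand-agnostically by default because sRNAs are routinely
produced from either strand of an annotated locus. Reads that only
straddle a boundary stay `unannotated`; the rule is sharp and cheap to
reason about, at the cost of dropping genuinely boundary-spanning
reads, which are rare at sRNA lengths.

# Quality checking

The diagnostics are deliberately simple statistics with known failure
signatures:

* **Size-class distributions and complexity.** Complexity is
  non-redundant/redundant count per size class, in $(0, 1]$; a sharp
  dip at 21–24 nt is the signature of a few dominant mature miRNAs,
  while uniformly high complexity at off-sizes indicates degradation.
* **Positional nucleotide composition**, count-weighted, to expose
  ligation and sequencing biases.
* **MA values** between replicates: $A = (a+b)/2$,
  $M = \log_2(b/a)$, computed only for sequences nonzero in both
  replicates. Zero-containing pairs are excluded and tallied rather
  than pseudo-counted: a diagnostic should not fabricate fold changes,
  and the exclusion count is itself informative.
* **Per-size fold-change quartiles** with a *centering score*, the
  maximum over size classes of $|\mathrm{median}\, M|$ — well-matched
  replicates give tight distributions symmetric about 0.
* **Top-N Jaccard index** on the N most abundant sequences (default
  N = 500; 1000 is also in common use and available via the `n`
  argument — both appear in practice and results should cite which was
  used). Ties at the N-th abundance are broken lexicographically so
  the statistic is deterministic.
* **Abundance windows**: nonzero abundances bucketed into
  $[kw, (k+1)w)$ ranges with per-bucket quartiles, because one boxplot
  over a distribution whose median sits in the noise range shows
  nothing.

Quartiles everywhere are the linear-interpolation "type 7" rule —
stated once, applied uniformly.

# Normalization

Six methods sit behind one interface, all preserving zeros exactly and
never producing negative values:

1. **Total count.** `value * T / colsum`. The total $T$ defaults to
   the *mean of the column sums* rather than the classic $10^6$:
   scaling 10 M-read libraries to 1 M shrinks all expression tenfold
   and can hide DE, and scaling small libraries up can fabricate it, so
   $T$ should live in the range of the actual library sizes.
2. **Upper quartile**, computed on *nonzero* values: sRNA matrices are
   zero-dominated, and the 75th percentile of a full column is often 0.
3. **TMM** with the canonical defaults (two-sided trims 0.30 on M and
   0.05 on A, precision weighting, reference = column whose nonzero
   upper-quartile proportion is closest to the mean). M and A are
   computed on library-size-scaled proportions, so a pure depth
   difference is absorbed by the library size and the factor stays 1;
   factors are rescaled to geometric mean 1. If fewer than 10
   sequences survive trimming the factor falls back to the untrimmed
   mean with a warning. The implementation is cross-checked against
   edgeR in the test suite.
4. **Median-of-ratios**: size factor = median over all-nonzero
   sequences of the count divided by its geometric mean across columns
   (cross-checked against DESeq2).
5. **Adapted quantile.** Classic rank-based quantile normalization
   with two count-specific rules: within-sample ties all receive the
   *average* of the reference values spanned by their ranks, and
   original zeros are pinned back to exactly 0. The reference
   distribution is the rank-wise mean of the sorted columns, zeros
   included. On tie-free, zero-free data this is ordinary quantile
   normalization (and idempotent).
6. **Subsampling** without replacement to the minimum library size
   (multivariate hypergeometric draws). A consistency scan first
   subsamples each column at proportions 0.9, 0.8, … and stops early
   if a two-sample KS test ($\alpha = 0.05$) finds the nonzero
   abundance distribution significantly changed before the target is
   reached. A bootstrap of `n_boot` subsamples at the target measures
   variability by pairwise KS distance — flagged high when the median
   pairwise distance exceeds the 95th percentile of
   subsample-to-original distances — and the *medoid* subsample
   (minimum summed distance) is returned, i.e. a representative
   rather than an arbitrary or outlying draw. The KS test, 0.1
   proportion grid and $\alpha$ are choices (a distribution-shape test
   was required and none was prescribed); all are arguments.

`evaluate_normalizations()` ranks methods by the between-replicate
centering score on the normalized matrix, under the assumption that
replicates carry no real DE. In end-to-end simulations with
heavy-tailed spiked loci, total-count normalization visibly suffers
the composition effect (a few massive DE sequences drag the column
sums, shifting every other sequence), which is why the pipeline default
is TMM; median-of-ratios behaves equivalently well.

# The noise offset

Degradation noise dominates low abundances, and a fold change between
two noise-level counts is meaningless. The estimator locates the
noise-to-signal boundary from strand bias: genuine sRNA loci are
strongly strand biased (transcripts come from one strand, or from a
hairpin arm), whereas degradation fragments hit both strands
indifferently.

The genome is tiled into windows (default 1000 nt). Each hit
contributes `count / n_hits` to its window — multi-mapped reads are
split so window totals conserve library totals — at its 5′-most
genomic coordinate. Windows are sorted by total abundance (with bias
as a tie-breaking secondary key, making the curve invariant to input
order) and grouped into consecutive *abundance levels* of at least 100
windows, so every strand-bias histogram has a stable sample size; the
level's abundance coordinate is its median window total. Per level,
biases are binned into 100 equal bins on $[0,1]$ and the KL divergence
from the uniform distribution is computed in bits:
$\sum_i p_i \log_2(p_i B)$. The base only rescales the curve and
cannot move its minimum; 100 bins is the point beyond which the curve
stops changing on data of realistic resolution.

The raw curve is smoothed by LOESS (degree 1, tricube weights, span
0.3, no robustness iterations) to keep a single outlying level from
faking a global minimum; for very short series the effective span is
widened to cover at least three points, since a local linear fit
degenerates below that. The *offset* of a sample is the abundance at
the global minimum of the smoothed curve (ties resolved to the
smallest abundance — the conservative choice, calling less noise
signal); the dataset offset is the minimum over samples, and curves
are computed per replicate with per-treatment minima also reported.

The shape is a dip, not a monotone slope: at very low totals a window
holds so few reads that its bias is forced toward 0, ½ or 1 (high
divergence), in the upper noise range many unbiased reads spread
biases broadly (low divergence), and above the boundary biased loci
concentrate mass again. The minimum therefore tracks the
noise-to-signal transition, and the estimate inherits the resolution
of the level grid — errors up to one level spacing are expected and
observed.

# Differential expression

Per treatment, a sequence's replicate values give a confidence
interval: the min–max interval when only two replicates exist (the
*maximal expression interval*), otherwise Chebyshev's
$\bar{x} \pm k s$, floored at 0. The default $k = 2$ gives
distribution-free coverage $\ge 1 - 1/k^2 = 75\%$; no distributional
assumption is made, which suits per-sequence counts whose dispersion
cannot be estimated from two or three replicates. $k$ is an argument
and widening it monotonically widens the interval.

A comparison is **S** when the closed intervals intersect (touching
endpoints count as overlap — the conservative reading, avoiding
knife-edge calls), **U** when the observed interval lies strictly
above the reference, **D** when strictly below. The amplitude is the
log2 offset fold change on the *proximate extremes* — the closest ends
of the two intervals:
$\mathrm{LOFC} = \log_2\frac{o + \text{offset}}{r + \text{offset}}$.
A provisional U/D with $|\mathrm{LOFC}| < 1$ is demoted to S; one
LOFC (a two-fold change) is the smallest difference typically
confirmable by Northern blot or qPCR, and the additive offset damps
ratios between noise-level counts so the ranking is not flooded by
them. For S calls an informational LOFC of the interval midpoints is
reported; it never participates in calling or ranking (the summary
convention for S calls was open; midpoints are symmetric and
scale-free).

Descriptors over the ordered comparisons concatenate into a pattern
string, sequences sort by their maximum |LOFC| over U/D comparisons
(all-S sequences last), and `cluster_patterns()` groups sequences by
exact pattern, reporting clusters with more than 15 members and
dropping the all-S cluster from the headline (most sequences are not
expected to change).

# The synthetic-data generator

`simulation_design()` encodes the study conditions the pipeline is
validated against; its defaults are fixed and the tests and the
acceptance script use them as-is.

* **Genome and loci**: 2 × 600 kb chromosomes (1200 windows of
  1000 nt, hence 12 abundance levels of 100 windows — enough
  resolution to localize the noise boundary while keeping a simulation
  under two seconds); 150 non-overlapping 150 nt loci, each emitting 5
  sequences (a dominant mature form at 50% of the locus total plus
  variants at 20/15/10/5%, the isomiR-like structure of real loci),
  lengths 21–24 nt; per-locus strand probability from Beta(0.2, 0.2),
  concentrated near 0 and 1 as real loci are.
* **Abundances**: noise reads are geometric with mean 1.8 (the
  exponential-like, singleton-dominated regime of real libraries) at
  ~12 positions per window, capped strictly below the designed noise
  ceiling $A_0 = 50$ per window; signal locus totals are truncated
  Pareto ($\alpha = 0.8$) above $A_0$ — heavy-tailed, like real miRNA
  expression spanning orders of magnitude.
* **Treatments**: 3 ordered treatments × 2 replicates. 30 loci are
  spiked with random non-trivial U/D/S patterns at 8-fold steps from
  miRNA-like baselines ≥ 1000 (spikes must sit well above the noise
  range to be recoverable under the abundance condition of the
  recovery analysis); multipliers are rescaled so the *minimum* across
  treatments is the baseline, keeping spiked loci above $A_0$ in every
  treatment (a "down" locus that fell into the noise range would
  contradict the strand-bias premise the offset estimator states).
* **Replicates** differ only by a library-size factor (drawn from
  U(0.8, 1.2), or fixed via `lib_size_factors`) and multiplicative
  log-normal noise with sd 0.1 — typical technical-replicate scatter.
  Counts are rounded; zeros are dropped.

Every read is an exact substring of the simulated genome, so exact
alignment recovers 100% genome matching by construction, and the
generator returns its designed alignments, window biases and
per-sequence patterns as machine-checkable truth.

What the generator does *not* emulate — sequencing errors, adapter
artifacts, ligation bias, correlated biological replicate structure,
whole-size-class perturbations (e.g. RNAi mutants losing an entire
class, for which no normalization in this package is adequate) — bounds
what passing tests show: they validate the estimators under the stated
noise model, not robustness to artifacts outside it.

# Numerical and degenerate-input conventions

* Quartiles: type 7 everywhere. KL: log base 2; bins closed on the
  left, with bias 1 in the last bin. Empty windows are excluded, and
  a size class with fewer than two shared sequences is omitted from
  fold-change summaries.
* Sequences sort lexicographically in every writer, so all outputs are
  byte-stable for a given input; ranking ties in `call_de()` break by
  sequence.
* Degenerate inputs fail loudly: zero column sums, empty size ranges,
  all-equal LOESS abscissae, histograms that do not sum to 1, fewer
  than two replicate values for an interval, no all-nonzero sequence
  for median-of-ratios.
* Randomness is confined to `normalize_subsampling()` (explicit
  `seed`) and the generator (explicit `seed`); everything else is
  deterministic.

# Known limitations

Exact matching only (no mismatch tolerance, by design); no dispersion
modeling or P-values — the LOFC threshold deliberately replaces them,
trading power for interpretability; the offset's resolution is the
abundance-level grid; Chebyshev intervals are conservative for small
$k$ only in coverage, not in width; subsampling discards reads and is
best used diagnostically; and the replicate evaluation assumes
replicates are exchangeable, which the QC stage must establish first.

# Problem sizes used in validation

The test suite and acceptance script run the generator at its default
scale (≈ 15,000 unique sequences, 1200 windows per replicate, 6
replicates) for end-to-end checks, a 20-seed replication of the offset
recovery, and smaller derived designs (25–60 loci, 100–300 kb) for
stage-level tests; these sizes were chosen to exercise every code path
at full statistical resolution of the level grid.
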