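# srnadekit

Quality checking, normalization and differential expression calling for
bulk small RNA (sRNA) sequencing data.

## The problem

sRNA-seq libraries differ from mRNA-seq in ways that break the default
DE toolbox: every unique 18–30 nt sequence is its own feature (no
aggregation into genes), abundances follow an exponential-like
distribution with the median deep inside the degradation-noise range,
and libraries are dominated by low-count reads. `srnadekit` implements
a pipeline built around those characteristics, for researchers who need
to decide which replicates to trust, which normalization renders them
comparable, where noise ends and signal begins, and which sequences
change expression across an ordered experiment.

## What it computes

- **Quality checks** per replicate and replicate pair: size-class
  distributions (redundant/non-redundant), per-size complexity
  (unique/total, in (0, 1]), positional nucleotide composition,
  genome-match percentages, MA (Bland–Altman) values, per-size log2
  fold-change quartiles, and the Jaccard index of the top-N most
  abundant reads.
- **Six normalizations** behind one interface: total count (RPM/RPT
  with a data-scaled total), upper quartile (of nonzero values), TMM,
  median-of-ratios (DESeq-style), a rank-based quantile normalization
  adapted for counts (within-sample ties share the average normalized
  value; zeros stay exactly zero), and subsampling without replacement
  to the minimum library size with a bootstrap representativeness
  check — plus a replicate-based evaluation that ranks methods by how
  well they center between-replicate fold-change distributions on 0.
- **Noise offset estimation.** Reads are assigned to genome windows
  (default 1000 nt); windows are grouped into abundance levels and the
  Kullback–Leibler divergence of each level's strand-bias histogram
  from the uniform distribution is computed. Degradation noise has no
  preferred strand, so the LOESS-smoothed KL curve (span 0.3) dips at
  the noise-to-signal boundary; the offset is the abundance at its
  global minimum.
- **CI/LOFC differential expression.** Per treatment, each sequence
  gets a confidence interval over replicates (min–max for two
  replicates, Chebyshev mean ± k·sd otherwise). Each comparison is
  called U (observed interval above the reference), D (below) or S
  (overlap), with the amplitude measured as the log2 offset fold
  change `LOFC = log2((a + offset)/(b + offset))` on the proximate
  interval ends; calls below 1 LOFC are demoted to S. Descriptors
  concatenate into patterns (e.g. `"US"`) that cluster sequences by
  expression trajectory.
- **A seeded synthetic-data generator** producing genomes, annotated
  loci, replicate libraries and complete ground truth, so every stage
  is testable without downloads.

## Worked example

```r
library(srnadekit)

sim <- simulate_experiment(simulation_design(), seed = 1)
m   <- build_expression_matrix(sim$libraries, sim$hierarchy)

# where does noise end?
wins <- experiment_window_profiles(m, sim$alignments, 1000)
est  <- estimate_offset(wins)
est$dataset_offset
#> [1] 49

# normalize and call differential expression patterns
nm <- normalize_tmm(m)$matrix
de <- call_de(nm, offset = est$dataset_offset)
head(de[, c("sequence", "pattern", "rank_lofc")], 3)
#>                   sequence pattern rank_lofc
#> 1   ACAGTAGCAGCTCACAGGTCCT      UU  3.207974
#> 2    ACGGGCCGCAATTTAGTACCA      UU  3.126490
#> 3 TTGAAAACTTGCCATTGGTCTACA      DD  3.100326

names(cluster_patterns(de)$headline)
#> [1] "DU" "UD" "UU"
```

The simulation's designed noise ceiling is 50, so the estimated offset
of 49 recovers the noise-to-signal boundary to within one abundance
level. The top-ranked sequences are spiked loci: their 8-fold steps
yield |LOFC| in excess of 3 on the proximate interval ends, while the
`pattern` column gives the direction of each consecutive-treatment
comparison; the headline clusters are the patterns with more than 15
member sequences (the all-S cluster is dropped).

`run_pipeline()` chains every stage (ingestion → alignment →
annotation → QC → normalization → offset → DE) from a single
`pipeline_config()` and writes per-stage TSV/JSON outputs plus a
parameter manifest; `inst/cli/srna-dekit.R` is a thin command-line
wrapper around it.

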