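#!/usr/bin/env Rscript

# Optional benchmark on the public H. sapiens hypoxia time series
# (GEO accession GSE47532: N00, H16, H32, H48, two replicates each).
# This is not run by the test suite: it needs the adapter-trimmed
# collapsed FASTA files for the eight replicates plus a human genome
# FASTA, downloaded separately. Given those, it reproduces the
# headline diagnostics: top-1000 replicate Jaccard indices (low for
# H16, > 0.8 elsewhere) and the dataset strand-bias KL offset
# (window 1000 nt, 100 bias bins, LOESS span 0.3).
#
# Usage:
#   Rscript scripts/benchmark_gse47532.R <reads_dir> <genome.fa> <out_dir>
# where <reads_dir> holds N00_1.fa ... H48_2.fa (count-suffix dialect).

suppressMessages(library(srnadekit))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 3L)
  stop("usage: benchmark_gse47532.R <reads_dir> <genome.fa> <out_dir>")
reads_dir <- args[1]; genome <- args[2]; out_dir <- args[3]

reps <- c(N00_1 = "N00_1.fa", N00_2 = "N00_2.fa", H16_1 = "H16_1.fa",
          H16_2 = "H16_2.fa", H32_1 = "H32_1.fa", H32_2 = "H32_2.fa",
          H48_1 = "H48_1.fa", H48_2 = "H48_2.fa")
libs <- lapply(names(reps), function(id)
  read_fasta_counts(file.path(reads_dir, reps[[id]]), "count_suffix",
                    replicate_id = id))
names(libs) <- names(reps)
hier <- sample_hierarchy(list(N00 = c("N00_1", "N00_2"),
                              H16 = c("H16_1", "H16_2"),
                              H32 = c("H32_1", "H32_2"),
                              H48 = c("H48_1", "H48_2")))
m <- build_expression_matrix(libs, hier)

jac <- sapply(names(hier$treatments), function(t) {
  rr <- hier$treatments[[t]]
  jaccard_top_n(libs[[rr[1]]], libs[[rr[2]]], 1000)
})
print(round(jac, 2))

aln <- align_reads_exact(
  read_library(setNames(rowSums(m$values), rownames(m$values)), "union"),
  genome)
wins <- experiment_window_profiles(m, aln, 1000)
est <- estimate_offset(wins, n_bias_bins = 100, span = 0.3)
print(est)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_offset_estimate(est, out_dir)
utils::write.table(data.frame(treatment = names(jac), jaccard_top1000 = jac),
                   file.path(out_dir, "jaccard_top1000.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
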