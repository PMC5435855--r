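test_that("plain FASTA records collapse with summed counts", {
  f <- withr::local_tempfile(fileext = ".fa")
  s <- strrep("ACGTA", 4)  # 20-mer
  writeLines(c(">r1", s, ">r2", s, ">r3", s, ">r4", "ACGTACGTACGTACGTACGTA"), f)
  lib <- read_fasta_counts(f, "plain")
  expect_equal(length(lib$counts), 2L)
  expect_equal(unname(lib$counts[s]), 3)
  expect_equal(redundant_total(lib), 4)
})

test_that("count_suffix headers supply abundances and reject junk", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seq1-534", "ACGTACGTACGTACGTACGTAC",
               ">seq2_12", "TTTTACGTACGTACGTACGTA"), f)
  lib <- read_fasta_counts(f, "count_suffix")
  expect_equal(unname(lib$counts["ACGTACGTACGTACGTACGTAC"]), 534)
  expect_equal(unname(lib$counts["TTTTACGTACGTACGTACGTA"]), 12)
  writeLines(c(">nocount", "ACGTACGTACGTACGTACGTAC"), f)
  expect_error(read_fasta_counts(f, "count_suffix"), "nocount")
})

test_that("empty input yields an empty library", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  lib <- read_fasta_counts(f, "plain")
  expect_equal(redundant_total(lib), 0)
  expect_equal(nonredundant_total(lib), 0L)
})

test_that("U is normalized to T and out-of-range lengths are dropped with a tally", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a-3", "ACGUACGUACGUACGUACGUA",   # RNA alphabet, 21 nt
               ">b-2", "ACGT",                     # too short
               ">c-5", strrep("ACGT", 10)), f)     # 40 nt, too long
  lib <- read_fasta_counts(f, "count_suffix")
  expect_equal(names(lib$counts), "ACGTACGTACGTACGTACGTA")
  expect_equal(attr(lib, "n_dropped"), 2L)
  expect_equal(attr(lib, "dropped_count"), 7)
})

test_that("count-suffix FASTA round-trips exactly", {
  set.seed(11)
  for (i in 1:3) {
    cn <- setNames(sample(1:500, 40), rand_seq(40, 22))
    lib <- read_library(cn, "repX")
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta_counts(lib, f)
    back <- read_fasta_counts(f, "count_suffix", replicate_id = "repX")
    expect_identical(back$counts, lib$counts)
  }
})

test_that("collapsing conserves redundant totals", {
  set.seed(3)
  seqs <- rand_seq(10, 20)
  cn <- setNames(sample(1:9, 30, replace = TRUE),
                 sample(seqs, 30, replace = TRUE))
  lib <- read_library(cn)
  expect_equal(redundant_total(lib), sum(cn))
  expect_lte(nonredundant_total(lib), 10L)
})

test_that("expression matrix is the zero-filled union over libraries", {
  libA <- read_library(c(ACGTACGTACGTACGTACGTA = 2), "A")
  libB <- read_library(c(TGCATGCATGCATGCATGCAT = 3), "B")
  h <- sample_hierarchy(list(T1 = "A", T2 = "B"))
  m <- build_expression_matrix(list(libA, libB), h)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(sum(m$values == 0), 2L)
  expect_equal(colSums(m$values), c(A = 2, B = 3))

  libB2 <- read_library(c(ACGTACGTACGTACGTACGTA = 5), "B")
  m2 <- build_expression_matrix(list(libA, libB2), h)
  expect_equal(m2$values["ACGTACGTACGTACGTACGTA", ], c(A = 2, B = 5))

  expect_error(build_expression_matrix(list(libA), h), "missing")
})

test_that("hierarchy validation rejects duplicates and empty treatments", {
  expect_error(sample_hierarchy(list(A = "r1", B = "r1")), "unique")
  expect_error(sample_hierarchy(list(A = character(0))), "at least one")
})

test_that("filter_matrix drops replicates (and emptied treatments) and size classes", {
  set.seed(5)
  seqs <- c(rand_seq(4, 20), rand_seq(4, 21), rand_seq(4, 22))
  v <- matrix(1, 12, 4, dimnames = list(seqs, c("a1", "a2", "b1", "b2")))
  m <- expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"),
                                            B = c("b1", "b2"))))
  f1 <- filter_matrix(m, drop_replicates = c("b1", "b2"))
  expect_equal(names(f1$hierarchy$treatments), "A")
  f2 <- filter_matrix(m, size_range = c(21, 21))
  expect_true(all(nchar(rownames(f2$values)) == 21))
  expect_equal(nrow(f2$values), 4L)
  f3 <- filter_matrix(m)
  expect_equal(f3$values, m$values)
  expect_error(filter_matrix(m, size_range = c(22, 21)), "interval")
})

test_that("exact aligner agrees with a brute-force both-strand scan", {
  set.seed(21)
  for (rep in 1:3) {
    gc <- c(chrA = paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = ""),
            chrB = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""))
    # reads: some planted (both strands), some random
    planted_p <- substr(gc[["chrA"]], 101, 121)
    planted_m <- chartr("ACGT", "TGCA",
                        paste(rev(strsplit(substr(gc[["chrB"]], 51, 71),
                                           "")[[1]]), collapse = ""))
    lib <- read_library(setNames(c(10, 5, 1, 1),
                                 c(planted_p, planted_m, rand_seq(2, 21))))
    genome <- Biostrings::DNAStringSet(gc)
    got <- align_reads_exact(lib, genome)
    want <- brute_force_align(lib, gc)
    expect_equal(got$hits, want$hits)
    # planted reads recovered at the right coordinates
    expect_true(any(got$hits$sequence == planted_p & got$hits$chrom == "chrA" &
                      got$hits$start == 100 & got$hits$strand == "+"))
    expect_true(any(got$hits$sequence == planted_m & got$hits$chrom == "chrB" &
                      got$hits$start == 50 & got$hits$strand == "-"))
  }
})

test_that("unmatched reads simply have no hits", {
  genome <- Biostrings::DNAStringSet(c(chr = strrep("A", 200)))
  lib <- read_library(setNames(5, strrep("C", 21)))
  aln <- align_reads_exact(lib, genome)
  expect_equal(nrow(aln$hits), 0L)
})

test_that("SAM loading converts coordinates and skips gapped records", {
  genome <- c(chr1 = 500L)
  seq1 <- "ACGTACGTACGTACGTACGTA"
  lib <- read_library(setNames(c(4, 2), c(seq1, "TTGCATTGCATTGCATTGCAT")))
  sam <- withr::local_tempfile(fileext = ".sam")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq1)))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:500",
    paste("q1", 0, "chr1", 101, 255, "21M", "*", 0, 0, seq1,
          "*", sep = "\t"),
    paste("q2", 16, "chr1", 201, 255, "21M", "*", 0, 0, rc,
          "*", sep = "\t"),
    paste("q3", 0, "chr1", 301, 255, "10M1I10M", "*", 0, 0,
          substr(seq1, 1, 21), "*", sep = "\t")), sam)
  aln <- load_alignments(sam, lib)
  expect_equal(nrow(aln$hits), 2L)
  expect_equal(attr(aln, "n_skipped_gapped"), 1L)
  plus <- aln$hits[aln$hits$strand == "+", ]
  expect_equal(plus$start, 100L)           # SAM 1-based -> internal 0-based
  minus <- aln$hits[aln$hits$strand == "-", ]
  expect_equal(minus$start, 200L)
  expect_equal(minus$sequence, seq1)       # read recovered by revcomp
})

test_that("BED loading keeps 0-based starts as-is", {
  seq1 <- "ACGTACGTACGTACGTACGTA"
  lib <- read_library(setNames(4, seq1))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr2", 100, 121, seq1, 0, "+", sep = "\t"), bed)
  aln <- load_alignments(bed, lib)
  expect_equal(aln$hits$start, 100)
  expect_equal(aln$hits$chrom, "chr2")
})

test_that("annotation uses full containment, strand-agnostic by default", {
  seq1 <- "ACGTACGTACGTACGTACGTA"  # 21-mer
  seq2 <- "TTGCATTGCATTGCATTGCAT"
  seq3 <- "GGGCCGGGCCGGGCCGGGCCG"
  hits <- data.frame(
    sequence = c(seq1, seq2), chrom = "chr1",
    start = c(100L, 125L), strand = c("-", "+"))
  aln <- alignment_set(hits, c(chr1 = 1000L))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmiRNA\t91\t130\t.\t+\t.\tID=mir1"), gff)
  cls <- annotate_reads(aln, gff, wanted_types = "miRNA",
                        library = read_library(setNames(c(1, 1, 1),
                                                        c(seq1, seq2, seq3))))
  # hit [100,121) inside feature [90,130) -> miRNA, despite strand mismatch
  expect_equal(cls$classes[[seq1]], "miRNA")
  # hit [125,146) overhangs the feature end -> unannotated
  expect_equal(cls$classes[[seq2]], "unannotated")
  # read with zero hits -> unannotated
  expect_equal(cls$classes[[seq3]], "unannotated")
})
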