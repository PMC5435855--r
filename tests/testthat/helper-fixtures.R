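# deterministic fixtures built in code

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# a tiny two-treatment, two-replicate matrix with known counts
tiny_matrix <- function(nseq = 30, seed = 1, factors = c(1, 1, 1, 1)) {
  set.seed(seed)
  seqs <- rand_seq(nseq, 21)
  base <- rpois(nseq, 40) + 1
  v <- sapply(factors, function(f) base * f)
  rownames(v) <- seqs
  colnames(v) <- c("a1", "a2", "b1", "b2")
  expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"), B = c("b1", "b2"))))
}

# brute-force both-strand exact-match oracle (independent of the
# PDict-based aligner)
brute_force_align <- function(library, genome_chars) {
  revcomp <- function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rows <- list()
  for (s in names(library$counts)) {
    rc <- revcomp(s)
    for (ch in names(genome_chars)) {
      g <- genome_chars[[ch]]
      L <- nchar(g); w <- nchar(s)
      for (i in seq_len(L - w + 1)) {
        sub <- substr(g, i, i + w - 1)
        if (sub == s)
          rows[[length(rows) + 1]] <- data.frame(
            sequence = s, chrom = ch, start = i - 1L, strand = "+")
        if (sub == rc)
          rows[[length(rows) + 1]] <- data.frame(
            sequence = s, chrom = ch, start = i - 1L, strand = "-")
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), strand = character(0))
  alignment_set(hits, vapply(genome_chars, nchar, integer(1)))
}

# a small simulation design that keeps unit tests fast
small_design <- function(...) {
  args <- list(chrom_lengths = c(chr1 = 1e5, chr2 = 1e5),
               n_loci = 25L, n_de_loci = 5L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_design, args)
}
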