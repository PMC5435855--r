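#' Describe a synthetic small RNA experiment
#'
#' The generator emulates the structure of a typical bulk sRNA-seq time
#' series: a random reference genome carrying strand-biased sRNA loci
#' with heavy-tailed abundances riding on a genome-wide carpet of
#' strand-unbiased, low-abundance degradation noise; 18-30 nt reads
#' with a 22-23 nt peak; ordered treatments with replicate pairs that
#' differ only by library-size factor and multiplicative noise; and a
#' subset of loci spiked with known fold changes between consecutive
#' treatments (the ground-truth U/D/S patterns).
#'
#' Noise windows stay strictly below the designed noise ceiling `A0`
#' with per-read strand drawn uniformly, while signal loci sit above
#' `A0` with per-locus strand bias drawn from a Beta concentrated near
#' 0 or 1 — the premise under which the strand-bias KL offset estimator
#' operates, so `A0` is the recoverable truth for
#' [estimate_offset()].
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_len Window length the noise ceiling is defined on.
#' @param n_loci Number of sRNA signal loci.
#' @param locus_length Length of each locus (nt).
#' @param seqs_per_locus Distinct read sequences per locus (a dominant
#'   mature sequence plus minor variants).
#' @param locus_split Abundance shares of the per-locus sequences.
#' @param n_de_loci Number of loci spiked with fold changes.
#' @param de_multiplier Fold change applied per U/D step of a spiked
#'   pattern.
#' @param de_base_min Minimum baseline abundance of spiked loci
#'   (abundant, miRNA-like, so spikes are well above the noise range).
#' @param noise_ceiling `A0`: designed noise-to-signal abundance
#'   boundary per window.
#' @param noise_positions_per_window Mean (Poisson) number of distinct
#'   noise reads per window.
#' @param noise_abundance_mean Mean abundance of a noise read
#'   (geometric, so the noise abundance distribution is
#'   exponential-like).
#' @param signal_alpha Pareto tail index of signal locus abundances
#'   (totals are `min * U^(-1/alpha)`, heavy-tailed above `A0`).
#' @param signal_cap Upper truncation of locus totals.
#' @param noise_sizes,noise_size_probs Read-length distribution of noise
#'   reads (default 18-30 nt peaking at 22-23).
#' @param signal_sizes,signal_size_probs Read-length distribution of
#'   locus reads (Dicer-typical 21-24 nt).
#' @param bias_beta `c(a, b)` of the Beta distribution for per-locus
#'   plus-strand probability (defaults concentrate near 0 and 1).
#' @param treatments Ordered treatment ids.
#' @param replicates_per_treatment Replicates per treatment.
#' @param replicate_noise_sd Std dev of multiplicative log-normal
#'   replicate noise.
#' @param lib_size_factors Per-replicate library-size factors (recycled);
#'   `NULL` draws them uniformly from `lib_size_range`.
#' @param lib_size_range Range library-size factors are drawn from.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(chrom_lengths = c(chr1 = 6e5, chr2 = 6e5),
                              window_len = 1000L,
                              n_loci = 150L,
                              locus_length = 150L,
                              seqs_per_locus = 5L,
                              locus_split = c(0.5, 0.2, 0.15, 0.1, 0.05),
                              n_de_loci = 30L,
                              de_multiplier = 8,
                              de_base_min = 1000,
                              noise_ceiling = 50,
                              noise_positions_per_window = 12,
                              noise_abundance_mean = 1.8,
                              signal_alpha = 0.8,
                              signal_cap = 1e5,
                              noise_sizes = 18:30,
                              noise_size_probs = c(1, 2, 4, 8, 20, 26, 20, 8, 4, 2, 1, 1, 1),
                              signal_sizes = 21:24,
                              signal_size_probs = c(0.25, 0.35, 0.3, 0.1),
                              bias_beta = c(0.2, 0.2),
                              treatments = c("T1", "T2", "T3"),
                              replicates_per_treatment = 2L,
                              replicate_noise_sd = 0.1,
                              lib_size_factors = NULL,
                              lib_size_range = c(0.8, 1.2)) {
  d <- as.list(environment())
  if (is.null(names(d$chrom_lengths)))
    names(d$chrom_lengths) <- paste0("chr", seq_along(d$chrom_lengths))
  if (d$n_de_loci > d$n_loci) stop("n_de_loci cannot exceed n_loci")
  if (length(d$locus_split) != d$seqs_per_locus)
    stop("locus_split must have seqs_per_locus entries")
  d$locus_split <- d$locus_split / sum(d$locus_split)
  d$noise_size_probs <- d$noise_size_probs / sum(d$noise_size_probs)
  d$signal_size_probs <- d$signal_size_probs / sum(d$signal_size_probs)
  if (length(d$noise_size_probs) != length(d$noise_sizes))
    stop("noise_size_probs must match noise_sizes")
  structure(d, class = "simulation_design")
}

random_chromosome <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

rpareto_trunc <- function(n, minimum, alpha, cap)
  pmin(minimum * stats::runif(n)^(-1 / alpha), cap)

# draws a U/D/S pattern of n_comp comparisons, never all-S
random_pattern <- function(n_comp) {
  repeat {
    p <- sample(c("U", "D", "S"), n_comp, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    if (any(p != "S")) return(paste(p, collapse = ""))
  }
}

# cumulative per-treatment multipliers from a pattern, rescaled so the
# minimum is 1 (spiked loci never fall below their baseline abundance)
pattern_multipliers <- function(pattern, de_multiplier) {
  steps <- strsplit(pattern, "")[[1]]
  m <- cumprod(c(1, vapply(steps, function(s)
    switch(s, U = de_multiplier, D = 1 / de_multiplier, S = 1), numeric(1))))
  m / min(m)
}

.sim_genome <- function(design) {
  genome <- Biostrings::DNAStringSet(
    vapply(design$chrom_lengths, random_chromosome, character(1)))
  names(genome) <- names(design$chrom_lengths)
  n <- design$n_loci
  len <- design$locus_length
  chrom <- sample(names(design$chrom_lengths), n, replace = TRUE,
                  prob = design$chrom_lengths)
  starts <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    L <- design$chrom_lengths[[ch]]
    if (length(i) * len > L)
      stop("loci do not fit on chromosome ", ch)
    # uniform non-overlapping placement: gaps + fixed locus widths
    slack <- L - length(i) * len
    starts[i] <- sort(sample.int(slack + 1L, length(i), replace = FALSE) - 1L) +
      (seq_along(i) - 1L) * len
  }
  is_de <- seq_len(n) %in% sample.int(n, design$n_de_loci)
  n_comp <- length(design$treatments) - 1L
  pattern <- ifelse(is_de,
                    vapply(seq_len(n), function(i)
                      if (is_de[i]) random_pattern(n_comp) else "", character(1)),
                    strrep("S", n_comp))
  loci <- data.frame(
    locus_id = sprintf("locus%03d", seq_len(n)),
    chrom = chrom, start = starts, end = starts + len,
    strand_p = stats::rbeta(n, design$bias_beta[1], design$bias_beta[2]),
    class = sample(c("miRNA", "siRNA", "tRNA"), n, replace = TRUE,
                   prob = c(0.5, 0.4, 0.1)),
    is_de = is_de, true_pattern = pattern, stringsAsFactors = FALSE)
  loci <- loci[order(loci$chrom, loci$start), ]
  loci$locus_id <- sprintf("locus%03d", seq_len(n))
  rownames(loci) <- NULL
  list(genome = genome, loci = loci)
}

#' Simulate a reference genome with annotated sRNA loci
#'
#' Deterministic under `seed`; loci never overlap.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return List with `genome` (`DNAStringSet`) and `loci` (data.frame:
#'   locus_id, chrom, start, end, strand_p, class, is_de,
#'   true_pattern).
#' @export
simulate_genome <- function(design, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  .sim_genome(design)
}

extract_reads <- function(genome_chars, chrom, start, len, strand) {
  s <- substring(genome_chars[chrom], start + 1L, start + len)
  minus <- strand == "-"
  if (any(minus))
    s[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(s[minus])))
  s
}

# enforce a strict per-window cap on noise totals; a count reduced to 0
# means the read is dropped by the caller
cap_window_counts <- function(counts, window_key, cap) {
  totals <- tapply(counts, window_key, sum)
  over <- names(totals)[totals >= cap]
  for (wk in over) {
    i <- which(window_key == wk)
    scale <- (cap - 1) / sum(counts[i])
    counts[i] <- pmax(1, floor(counts[i] * scale))
    while (sum(counts[i]) >= cap) {
      j <- i[which.max(counts[i])]
      counts[j] <- counts[j] - 1
    }
  }
  counts
}

#' Simulate a full multi-treatment sRNA-seq experiment
#'
#' Generates a genome ([simulate_genome()] under the same seed), a
#' master read table (every read an exact substring of the genome, so
#' exact alignment recovers 100% genome matching), and per-replicate
#' libraries obtained by scaling baseline abundances with the
#' treatment's spiked multipliers, the replicate's library-size factor
#' and multiplicative log-normal noise.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed; the whole experiment is reproducible.
#' @return List of class `srna_simulation`: `design`, `seed`, `genome`,
#'   `loci`, `libraries` (named list of [read_library()]),
#'   `hierarchy`, `alignments` (designed positions as an
#'   [alignment_set()]), and `truth` with `per_sequence` (sequence,
#'   locus_id, class, is_de, true_pattern, step_fc, base),
#'   `windows` (designed per-window strand bias), `noise_ceiling` and
#'   `lib_factors`.
#' @export
simulate_experiment <- function(design, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- .sim_genome(design)
  genome_chars <- stats::setNames(as.character(g$genome), names(g$genome))
  A0 <- design$noise_ceiling

  ## signal reads
  loci <- g$loci
  n_loci <- nrow(loci)
  loci$total <- ifelse(loci$is_de,
                       rpareto_trunc(n_loci, design$de_base_min,
                                     design$signal_alpha, design$signal_cap),
                       rpareto_trunc(n_loci, A0, design$signal_alpha,
                                     design$signal_cap))
  k <- design$seqs_per_locus
  li <- rep(seq_len(n_loci), each = k)
  sig_len <- sample(design$signal_sizes, n_loci * k, replace = TRUE,
                    prob = design$signal_size_probs)
  sig_off <- floor(stats::runif(n_loci * k) *
                     (design$locus_length - sig_len + 1))
  sig_start <- loci$start[li] + sig_off
  sig_strand <- ifelse(stats::runif(n_loci * k) < loci$strand_p[li], "+", "-")
  sig_base <- loci$total[li] * rep(design$locus_split, times = n_loci)
  sig <- data.frame(
    chrom = loci$chrom[li], start = sig_start, length = sig_len,
    strand = sig_strand, base = sig_base, locus_id = loci$locus_id[li],
    class = loci$class[li], is_de = loci$is_de[li],
    true_pattern = loci$true_pattern[li], stringsAsFactors = FALSE)

  ## noise reads: a carpet of low-abundance, strand-unbiased positions
  noise <- list()
  for (ch in names(design$chrom_lengths)) {
    L <- design$chrom_lengths[[ch]]
    win_lo <- seq(0, L - 1, by = design$window_len)
    win_hi <- pmin(win_lo + design$window_len, L)
    n_pos <- stats::rpois(length(win_lo), design$noise_positions_per_window)
    wi <- rep(seq_along(win_lo), n_pos)
    N <- length(wi)
    if (!N) next
    len <- sample(design$noise_sizes, N, replace = TRUE,
                  prob = design$noise_size_probs)
    room <- win_hi[wi] - win_lo[wi] - len
    ok <- room >= 0
    wi <- wi[ok]; len <- len[ok]; room <- room[ok]
    start <- win_lo[wi] + floor(stats::runif(length(wi)) * (room + 1))
    cnt <- 1 + stats::rgeom(length(wi),
                            prob = 1 / design$noise_abundance_mean)
    cnt <- cap_window_counts(cnt, paste(ch, wi), A0)
    strand <- ifelse(stats::runif(length(wi)) < 0.5, "+", "-")
    keep <- cnt > 0
    noise[[ch]] <- data.frame(
      chrom = ch, start = start[keep], length = len[keep],
      strand = strand[keep], base = cnt[keep],
      locus_id = NA_character_, class = "noise",
      is_de = FALSE, true_pattern = strrep("S", length(design$treatments) - 1L),
      stringsAsFactors = FALSE)
  }
  reads <- rbind(sig, do.call(rbind, noise))
  reads$sequence <- extract_reads(genome_chars, reads$chrom, reads$start,
                                  reads$length, reads$strand)

  ## collapse chance sequence collisions (keep dominant row's metadata)
  reads <- reads[order(-reads$base), ]
  dup <- duplicated(reads$sequence)
  if (any(dup)) {
    extra <- tapply(reads$base[dup], reads$sequence[dup], sum)
    reads <- reads[!dup, ]
    add <- extra[reads$sequence]
    reads$base <- reads$base + ifelse(is.na(add), 0, add)
  }
  rownames(reads) <- NULL

  ## per-treatment multipliers
  n_trt <- length(design$treatments)
  mult <- matrix(1, nrow(reads), n_trt,
                 dimnames = list(NULL, design$treatments))
  de_rows <- which(reads$is_de)
  for (i in de_rows)
    mult[i, ] <- pattern_multipliers(reads$true_pattern[i],
                                     design$de_multiplier)

  ## replicate libraries
  rep_ids <- unlist(lapply(design$treatments, function(t)
    paste0(t, "_r", seq_len(design$replicates_per_treatment))))
  trt_of <- rep(design$treatments, each = design$replicates_per_treatment)
  lib_f <- design$lib_size_factors
  if (is.null(lib_f))
    lib_f <- stats::runif(length(rep_ids), design$lib_size_range[1],
                          design$lib_size_range[2])
  lib_f <- stats::setNames(rep_len(lib_f, length(rep_ids)), rep_ids)
  libraries <- vector("list", length(rep_ids))
  names(libraries) <- rep_ids
  for (j in seq_along(rep_ids)) {
    mu <- reads$base * mult[, trt_of[j]] * lib_f[[j]]
    cnt <- round(mu * exp(stats::rnorm(length(mu), 0,
                                       design$replicate_noise_sd)))
    keep <- cnt > 0
    libraries[[j]] <- read_library(
      stats::setNames(cnt[keep], reads$sequence[keep]), rep_ids[j],
      size_range = range(c(design$noise_sizes, design$signal_sizes)))
  }
  hierarchy <- sample_hierarchy(stats::setNames(
    split(rep_ids, factor(trt_of, levels = design$treatments)),
    design$treatments))

  ## designed alignments and window truth
  aln <- alignment_set(reads[, c("sequence", "chrom", "start", "strand")],
                       stats::setNames(as.integer(design$chrom_lengths),
                                       names(design$chrom_lengths)))
  five <- ifelse(reads$strand == "+", reads$start,
                 reads$start + reads$length - 1L)
  wkey <- paste(reads$chrom, floor(five / design$window_len), sep = ":")
  plus <- tapply(reads$base * (reads$strand == "+"), wkey, sum)
  tot <- tapply(reads$base, wkey, sum)
  win_truth <- data.frame(window = names(tot), total = as.numeric(tot),
                          bias = as.numeric(plus[names(tot)]) / as.numeric(tot))

  structure(list(
    design = design, seed = seed, genome = g$genome, loci = loci,
    libraries = libraries, hierarchy = hierarchy, alignments = aln,
    truth = list(
      per_sequence = data.frame(
        sequence = reads$sequence, locus_id = reads$locus_id,
        class = reads$class, is_de = reads$is_de,
        true_pattern = reads$true_pattern,
        step_fc = ifelse(reads$is_de, design$de_multiplier, 1),
        base = reads$base, stringsAsFactors = FALSE),
      windows = win_truth, noise_ceiling = A0, lib_factors = lib_f)),
    class = "srna_simulation")
}

#' @export
print.srna_simulation <- function(x, ...) {
  cat(sprintf(paste0("srna_simulation (seed %d): %d loci (%d spiked), ",
                     "%d treatments x %d replicates, %d unique reads\n"),
              x$seed, nrow(x$loci), sum(x$loci$is_de),
              length(x$design$treatments), x$design$replicates_per_treatment,
              nrow(x$truth$per_sequence)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits `genome.fa`, one count-suffix FASTA per replicate
#' (`reads_<replicate>.fa`), `loci.gff3` (truth annotation),
#' `truth.tsv` (per-sequence ground truth) and `hierarchy.json`.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  for (id in names(sim$libraries))
    write_fasta_counts(sim$libraries[[id]],
                       file.path(dir, paste0("reads_", id, ".fa")))
  gr <- GenomicRanges::GRanges(
    seqnames = sim$loci$chrom,
    ranges = IRanges::IRanges(start = sim$loci$start + 1L, end = sim$loci$end),
    strand = ifelse(sim$loci$strand_p >= 0.5, "+", "-"),
    type = sim$loci$class, ID = sim$loci$locus_id,
    source = "srnadekit_simulation")
  rtracklayer::export(gr, file.path(dir, "loci.gff3"), format = "gff3")
  utils::write.table(sim$truth$per_sequence, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(treatments = sim$hierarchy$treatments,
         noise_ceiling = sim$truth$noise_ceiling,
         seed = sim$seed),
    file.path(dir, "hierarchy.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
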