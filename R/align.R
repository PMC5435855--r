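#' Construct an alignment set
#'
#' @param hits data.frame with columns `sequence`, `chrom`, `start`
#'   (0-based), `strand` (`+`/`-`). One row per genomic occurrence.
#' @param genome_lengths Named integer vector of chromosome lengths.
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(hits, genome_lengths) {
  need <- c("sequence", "chrom", "start", "strand")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  hits <- hits[, need]
  hits <- hits[order(hits$sequence, hits$chrom, hits$start, hits$strand,
                     method = "radix"), ]
  rownames(hits) <- NULL
  structure(list(hits = hits, genome_lengths = genome_lengths),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d hits over %d sequences, %d chromosome(s)\n",
              nrow(x$hits), length(unique(x$hits$sequence)),
              length(x$genome_lengths)))
  invisible(x)
}

#' Number of genomic hits per sequence
#' @param alignments An `alignment_set`.
#' @return Named integer vector (sequences with >= 1 hit only).
#' @export
hit_counts <- function(alignments) {
  if (!nrow(alignments$hits)) return(integer(0))
  tab <- table(alignments$hits$sequence)
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

read_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L) {
    if (!file.exists(genome)) stop("cannot read genome FASTA: ", genome)
    return(Biostrings::readDNAStringSet(genome))
  }
  stop("genome must be a FASTA path or a DNAStringSet")
}

#' Exact full-length alignment of short reads to a genome
#'
#' Every unique read sequence is matched against both strands of the
#' reference, reporting all occurrences of exact, full-length, ungapped
#' matches. This is the regime appropriate for 18-30 nt small RNAs; no
#' mismatch tolerance is offered. A minus-strand hit at 0-based start
#' `s` means the read equals the reverse complement of
#' `genome[s, s + length)`.
#'
#' @param library A [read_library()]; reads must be N-free.
#' @param genome FASTA path or `DNAStringSet`.
#' @return An [alignment_set()]. Reads with no match simply have no rows.
#' @export
align_reads_exact <- function(library, genome) {
  gen <- read_genome(genome)
  if (is.null(names(gen))) stop("genome sequences must be named")
  names(gen) <- sub("\\s.*$", "", names(gen))
  glens <- stats::setNames(Biostrings::width(gen), names(gen))
  seqs <- names(library$counts)
  out <- list()
  if (length(seqs)) {
    widths <- nchar(seqs)
    for (w in sort(unique(widths))) {
      sw <- seqs[widths == w]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sw))
      for (ci in seq_along(gen)) {
        chrom <- names(gen)[ci]
        L <- glens[[chrom]]
        mp <- Biostrings::matchPDict(pd, gen[[ci]])
        st <- Biostrings::startIndex(mp)
        n_per <- lengths(st)
        if (sum(n_per)) {
          out[[length(out) + 1L]] <- data.frame(
            sequence = rep(sw, n_per),
            chrom = chrom,
            start = unlist(st, use.names = FALSE) - 1L,
            strand = "+", stringsAsFactors = FALSE)
        }
        mm <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(gen[[ci]]))
        st <- Biostrings::startIndex(mm)
        n_per <- lengths(st)
        if (sum(n_per)) {
          rc_start <- unlist(st, use.names = FALSE)  # 1-based on revcomp
          out[[length(out) + 1L]] <- data.frame(
            sequence = rep(sw, n_per),
            chrom = chrom,
            start = L - rc_start - w + 1L,
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), strand = character(0))
  alignment_set(hits, glens)
}

#' Load precomputed alignments from SAM or BED
#'
#' Records are matched back to library sequences (by the aligned sequence
#' for SAM, reverse-complemented for minus-strand records; by the
#' name-encoded sequence for BED). Only ungapped, unclipped, full-length
#' records are kept; others are skipped with a tally. Coordinates are
#' converted to the internal 0-based half-open convention (SAM is
#' 1-based; BED already 0-based).
#'
#' @param path SAM (`.sam`) or BED (`.bed`) file.
#' @param library The [read_library()] the alignments belong to.
#' @param format `"auto"` (from extension), `"sam"` or `"bed"`.
#' @return An [alignment_set()] with attributes `n_skipped_gapped` and
#'   `n_skipped_unknown` tallying rejected records.
#' @export
load_alignments <- function(path, library, format = c("auto", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bed = "bed",
                     stop("cannot infer alignment format from extension: ", path))
  if (format == "sam") load_sam_alignments(path, library)
  else load_bed_alignments(path, library)
}

load_sam_alignments <- function(path, library) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "cigar", "seq"),
                               flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$pos)
  if (n == 0L)
    return(alignment_set(data.frame(sequence = character(0), chrom = character(0),
                                    start = integer(0), strand = character(0)),
                         hdr))
  ungapped <- grepl("^[0-9]+M$", rec$cigar)
  seq_fwd <- as.character(rec$seq)
  minus <- as.character(rec$strand) == "-"
  seq_read <- seq_fwd
  if (any(minus))
    seq_read[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq_fwd[minus])))
  known <- seq_read %in% names(library$counts)
  keep <- ungapped & known
  n_unknown <- sum(ungapped & !known)
  if (n_unknown)
    warning(n_unknown, " SAM record(s) whose sequence is not in the library; skipped")
  hits <- data.frame(sequence = seq_read[keep],
                     chrom = as.character(rec$rname)[keep],
                     start = rec$pos[keep] - 1L,
                     strand = as.character(rec$strand)[keep],
                     stringsAsFactors = FALSE)
  res <- alignment_set(hits, hdr)
  attr(res, "n_skipped_gapped") <- sum(!ungapped)
  attr(res, "n_skipped_unknown") <- n_unknown
  res
}

load_bed_alignments <- function(path, library) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(bed) < 4L) stop("BED file needs at least 4 columns (name = sequence)")
  strand <- if (ncol(bed) >= 6L) bed[[6]] else rep("+", nrow(bed))
  seqs <- toupper(bed[[4]])
  full_len <- nchar(seqs) == (bed[[3]] - bed[[2]])
  known <- seqs %in% names(library$counts)
  keep <- full_len & known
  n_unknown <- sum(full_len & !known)
  if (n_unknown)
    warning(n_unknown, " BED record(s) whose sequence is not in the library; skipped")
  hits <- data.frame(sequence = seqs[keep], chrom = bed[[1]][keep],
                     start = bed[[2]][keep], strand = strand[keep],
                     stringsAsFactors = FALSE)
  glens <- tapply(bed[[3]], bed[[1]], max)
  res <- alignment_set(hits, stats::setNames(as.integer(glens), names(glens)))
  attr(res, "n_skipped_gapped") <- sum(!full_len)
  attr(res, "n_skipped_unknown") <- n_unknown
  res
}

#' Classify aligned reads by GFF3 annotation
#'
#' A read is assigned annotation class `C` when at least one of its
#' genomic hits is fully contained within a feature of type `C`
#' (strand-agnostic by default, since small RNAs can arise from either
#' strand of an annotated locus). Reads with hits but no containing
#' feature, and reads with no hits at all, are classified `unannotated`.
#'
#' @param alignments An [alignment_set()].
#' @param gff Path to a GFF3 file (1-based inclusive coordinates) or a
#'   `GRanges` with a `type` column.
#' @param wanted_types Feature types to classify against (non-empty).
#' @param strand_aware If `TRUE`, require the hit strand to match the
#'   feature strand.
#' @param library Optional [read_library()]; its sequences without hits
#'   are included as `unannotated`.
#' @return List with element `classes`: named list mapping sequence to a
#'   character vector of class labels.
#' @export
annotate_reads <- function(alignments, gff, wanted_types,
                           strand_aware = FALSE, library = NULL) {
  if (!length(wanted_types)) stop("wanted_types must be non-empty")
  feats <- if (inherits(gff, "GRanges")) gff else rtracklayer::import(gff)
  feats <- feats[as.character(feats$type) %in% wanted_types]
  hits <- alignments$hits
  seqs <- unique(hits$sequence)
  classes <- stats::setNames(vector("list", length(seqs)), seqs)
  if (nrow(hits) && length(feats)) {
    gr <- GenomicRanges::GRanges(
      seqnames = hits$chrom,
      ranges = IRanges::IRanges(start = hits$start + 1L,
                                width = nchar(hits$sequence)),
      strand = hits$strand)
    ov <- GenomicRanges::findOverlaps(gr, feats, type = "within",
                                      ignore.strand = !strand_aware)
    if (length(ov)) {
      df <- data.frame(seq = hits$sequence[S4Vectors::queryHits(ov)],
                       cls = as.character(feats$type)[S4Vectors::subjectHits(ov)])
      sp <- split(df$cls, df$seq)
      for (s in names(sp)) classes[[s]] <- sort(unique(sp[[s]]))
    }
  }
  empty <- vapply(classes, is.null, logical(1))
  classes[empty] <- list("unannotated")
  if (!is.null(library)) {
    missing <- setdiff(names(library$counts), names(classes))
    add <- stats::setNames(rep(list("unannotated"), length(missing)), missing)
    classes <- c(classes, add)
  }
  list(classes = classes)
}

#' Sequences carrying a given annotation class
#' @param classification Result of [annotate_reads()].
#' @param class Class label, e.g. `"miRNA"`.
#' @return Character vector of sequences.
#' @export
sequences_of_class <- function(classification, class) {
  hit <- vapply(classification$classes, function(cl) class %in% cl, logical(1))
  names(classification$classes)[hit]
}
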