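#' Size-class distribution of a read library
#'
#' @param library A [read_library()].
#' @param mode `"redundant"` counts every sequenced read (abundance
#'   weighted); `"nonredundant"` counts distinct sequences.
#' @return Named numeric vector, size class (nt) -> count. Sums to the
#'   redundant total or to the number of unique sequences respectively.
#' @export
size_class_distribution <- function(library, mode = c("redundant", "nonredundant")) {
  mode <- match.arg(mode)
  if (!length(library$counts)) return(stats::setNames(numeric(0), character(0)))
  len <- nchar(names(library$counts))
  w <- if (mode == "redundant") library$counts else rep(1, length(len))
  agg <- tapply(w, len, sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Per-size complexity (unique / total reads)
#'
#' Complexity close to 1 indicates many distinct low-abundance sequences;
#' low complexity indicates a few dominant sequences (typical of miRNA
#' size classes).
#'
#' @param library A [read_library()].
#' @return Named numeric vector, size -> non-redundant / redundant count,
#'   in (0, 1]. Sizes with no reads are omitted.
#' @export
complexity_per_size <- function(library) {
  red <- size_class_distribution(library, "redundant")
  nonred <- size_class_distribution(library, "nonredundant")
  out <- nonred[names(red)] / red
  out[red > 0]
}

#' Jaccard similarity of the top-N most abundant reads of two libraries
#'
#' Replicate comparability diagnostic: `|topA n topB| / |topA u topB|`
#' on the N most abundant sequences of each library. Ties at the N-th
#' abundance are broken lexicographically by sequence, so the result is
#' deterministic. When a library holds fewer than `n` sequences, all of
#' them are used.
#'
#' @param libA,libB [read_library()] objects.
#' @param n Number of top sequences (default 500; 1000 is also common).
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_top_n <- function(libA, libB, n = 500L) {
  if (n <= 0) stop("n must be a positive integer")
  top <- function(lib) {
    cn <- lib$counts
    ord <- order(-cn, names(cn), method = "radix")
    names(cn)[ord][seq_len(min(n, length(cn)))]
  }
  a <- top(libA); b <- top(libB)
  u <- union(a, b)
  if (!length(u)) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

#' MA (Bland-Altman) values between two replicates
#'
#' One point per sequence with nonzero abundance in both replicates:
#' `A = (a + b) / 2` and `M = log2(b / a)`. Pairs containing a zero are
#' excluded (no pseudo-count is fabricated) and tallied in the
#' `n_excluded` attribute.
#'
#' @param repA,repB Numeric abundance vectors aligned on the same
#'   sequence index (names optional but must match if present).
#' @return data.frame with columns `A` and `M` (and `sequence` when the
#'   inputs are named); attribute `n_excluded`.
#' @export
ma_values <- function(repA, repB) {
  if (length(repA) != length(repB))
    stop("abundance vectors must have equal length")
  if (!is.null(names(repA)) && !is.null(names(repB)) &&
      !identical(names(repA), names(repB)))
    stop("abundance vectors are not aligned on the same sequences")
  keep <- repA > 0 & repB > 0
  df <- data.frame(A = (repA[keep] + repB[keep]) / 2,
                   M = log2(repB[keep] / repA[keep]))
  if (!is.null(names(repA))) df$sequence <- names(repA)[keep]
  rownames(df) <- NULL
  attr(df, "n_excluded") <- sum(!keep & (repA > 0 | repB > 0))
  df
}

type7_quartiles <- function(x)
  stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)

#' Per-size-class fold-change distribution between two replicates
#'
#' For each size class with at least two sequences nonzero in both
#' libraries, the quartiles (linear-interpolation "type 7" rule) of the
#' log2 fold changes M are reported. Well-matched replicates show tight
#' distributions symmetric on 0; the `centering_score` attribute is the
#' maximum over sizes of |median M|.
#'
#' @param repA,repB [read_library()] objects.
#' @return data.frame with columns `size`, `n`, `q1`, `median`, `q3`;
#'   attribute `centering_score`.
#' @export
fold_change_distribution_per_size <- function(repA, repB) {
  shared <- intersect(names(repA$counts), names(repB$counts))
  out <- data.frame(size = integer(0), n = integer(0), q1 = numeric(0),
                    median = numeric(0), q3 = numeric(0))
  if (length(shared)) {
    m <- log2(repB$counts[shared] / repA$counts[shared])
    size <- nchar(shared)
    rows <- lapply(sort(unique(size)), function(s) {
      ms <- m[size == s]
      if (length(ms) < 2L) return(NULL)
      q <- type7_quartiles(ms)
      data.frame(size = s, n = length(ms), q1 = q[1], median = q[2], q3 = q[3])
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  attr(out, "centering_score") <-
    if (nrow(out)) max(abs(out$median)) else NA_real_
  out
}

#' Percentage of genome-matching reads
#'
#' @param library A [read_library()].
#' @param alignments [alignment_set()] computed for this library.
#' @param mode `"redundant"` weights sequences by abundance;
#'   `"nonredundant"` counts distinct sequences.
#' @return List with `overall` (percentage in \[0, 100\]) and `per_size`
#'   (named vector of percentages by size class).
#' @export
genome_match_percent <- function(library, alignments,
                                 mode = c("redundant", "nonredundant")) {
  mode <- match.arg(mode)
  seqs <- names(library$counts)
  if (!length(seqs)) return(list(overall = NA_real_, per_size = numeric(0)))
  matched <- seqs %in% unique(alignments$hits$sequence)
  w <- if (mode == "redundant") library$counts else rep(1, length(seqs))
  size <- nchar(seqs)
  overall <- 100 * sum(w[matched]) / sum(w)
  per_size <- vapply(sort(unique(size)), function(s) {
    i <- size == s
    100 * sum(w[i & matched]) / sum(w[i])
  }, numeric(1))
  names(per_size) <- sort(unique(size))
  list(overall = overall, per_size = per_size)
}

#' Positional nucleotide composition of a library
#'
#' Count-weighted base frequencies at each read position, a standard
#' check for ligation or sequencing biases (e.g. the 5' U preference of
#' many miRNAs).
#'
#' @param library A [read_library()].
#' @return Numeric matrix, positions x bases (A, C, G, T); each row with
#'   data sums to 1.
#' @export
positional_composition <- function(library) {
  bases <- c("A", "C", "G", "T")
  seqs <- names(library$counts)
  if (!length(seqs))
    return(matrix(numeric(0), ncol = 4, dimnames = list(NULL, bases)))
  maxlen <- max(nchar(seqs))
  comp <- matrix(0, nrow = maxlen, ncol = 4,
                 dimnames = list(seq_len(maxlen), bases))
  cnt <- library$counts
  for (p in seq_len(maxlen)) {
    ch <- substr(seqs, p, p)
    has <- ch != ""
    if (!any(has)) next
    agg <- tapply(cnt[has], factor(ch[has], levels = bases), sum)
    agg[is.na(agg)] <- 0
    comp[p, ] <- agg / sum(agg)
  }
  comp
}

#' Abundance-window summaries of an expression matrix
#'
#' Small RNA abundance distributions are dominated by low counts, so a
#' single boxplot per sample is uninformative. Nonzero abundances are
#' instead bucketed into ranges `[k*w, (k+1)*w)` of user-defined width
#' `w` and the per-replicate distribution is summarized within each
#' bucket.
#'
#' @param matrix An [expr_matrix()].
#' @param window_width Positive bucket width `w`.
#' @return data.frame with columns `replicate`, `window_lo`, `window_hi`,
#'   `n`, `q1`, `median`, `q3`.
#' @export
abundance_window_summary <- function(matrix, window_width) {
  if (window_width <= 0) stop("window_width must be > 0")
  rows <- list()
  for (rep in colnames(matrix$values)) {
    v <- matrix$values[, rep]
    v <- v[v > 0]
    if (!length(v)) next
    k <- floor(v / window_width)
    for (kk in sort(unique(k))) {
      vv <- v[k == kk]
      q <- type7_quartiles(vv)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, window_lo = kk * window_width,
        window_hi = (kk + 1) * window_width, n = length(vv),
        q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(replicate = character(0), window_lo = numeric(0),
                      window_hi = numeric(0), n = integer(0), q1 = numeric(0),
                      median = numeric(0), q3 = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

restrict_library <- function(library, sequences) {
  cn <- library$counts[names(library$counts) %in% sequences]
  structure(list(replicate_id = library$replicate_id, counts = cn),
            class = "read_library")
}

#' Full quality-check report for an experiment
#'
#' Assembles, per replicate: size-class distributions (redundant and
#' non-redundant), complexity profile, positional nucleotide composition
#' and (when alignments are supplied) genome-match percentages; and per
#' replicate pair within each treatment: top-N Jaccard index, MA values
#' and per-size fold-change quartiles with centering scores. The report
#' can be computed on raw or normalized matrices and restricted to the
#' sequences of one annotation class.
#'
#' @param matrix An [expr_matrix()] (raw or normalized).
#' @param alignments Optional [alignment_set()].
#' @param classification Optional result of [annotate_reads()].
#' @param top_n Top-N for the Jaccard index (default 500).
#' @param abundance_window Optional width for
#'   [abundance_window_summary()].
#' @param class Optional annotation class label restricting the report.
#' @return An object of class `qc_report` (a nested list; see
#'   [write_qc_report()]).
#' @export
qc_report <- function(matrix, alignments = NULL, classification = NULL,
                      top_n = 500L, abundance_window = NULL, class = NULL) {
  if (!is.null(class)) {
    if (is.null(classification))
      stop("class restriction requires a classification")
    keep <- sequences_of_class(classification, class)
    matrix <- expr_matrix(
      matrix$values[rownames(matrix$values) %in% keep, , drop = FALSE],
      matrix$hierarchy, matrix$normalized_by)
  }
  reps <- colnames(matrix$values)
  libs <- lapply(reps, function(r) matrix_column_library(matrix, r))
  names(libs) <- reps
  per_replicate <- lapply(reps, function(r) {
    lib <- libs[[r]]
    res <- list(
      replicate = r,
      redundant_total = redundant_total(lib),
      nonredundant_total = nonredundant_total(lib),
      size_class_redundant = size_class_distribution(lib, "redundant"),
      size_class_nonredundant = size_class_distribution(lib, "nonredundant"),
      complexity = complexity_per_size(lib),
      composition = positional_composition(lib))
    if (!is.null(alignments)) {
      res$genome_match_redundant <- genome_match_percent(lib, alignments, "redundant")
      res$genome_match_nonredundant <- genome_match_percent(lib, alignments, "nonredundant")
    }
    res
  })
  names(per_replicate) <- reps
  pairs <- list()
  for (trt in names(matrix$hierarchy$treatments)) {
    rr <- matrix$hierarchy$treatments[[trt]]
    if (length(rr) < 2L) next
    cmb <- utils::combn(rr, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      fc <- fold_change_distribution_per_size(libs[[a]], libs[[b]])
      pairs[[paste(a, b, sep = "|")]] <- list(
        treatment = trt, repA = a, repB = b,
        jaccard = jaccard_top_n(libs[[a]], libs[[b]], top_n),
        ma = ma_values(matrix$values[, a], matrix$values[, b]),
        fold_change_per_size = fc,
        centering_score = attr(fc, "centering_score"))
    }
  }
  rep <- list(per_replicate = per_replicate, pairs = pairs,
              normalized_by = matrix$normalized_by,
              top_n = top_n, class = class)
  if (!is.null(abundance_window))
    rep$abundance_windows <- abundance_window_summary(matrix, abundance_window)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report (%s%s): %d replicates, %d replicate pairs\n",
              if (nzchar(x$normalized_by)) x$normalized_by else "raw",
              if (!is.null(x$class)) paste0(", class ", x$class) else "",
              length(x$per_replicate), length(x$pairs)))
  invisible(x)
}

#' Serialize a QC report to TSV tables and a JSON summary
#'
#' Writes `size_class.tsv`, `complexity.tsv`, `composition.tsv`,
#' `jaccard.tsv`, `ma_points.tsv`, `fold_change_per_size.tsv`, optional
#' `genome_match.tsv` and `abundance_windows.tsv`, plus `summary.json`
#' (totals, Jaccard indices and centering scores).
#'
#' @param report A [qc_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(rbind, lapply(report$per_replicate, function(p) {
    sizes <- union(names(p$size_class_redundant), names(p$size_class_nonredundant))
    sizes <- sizes[order(as.integer(sizes))]
    data.frame(replicate = p$replicate, size = as.integer(sizes),
               redundant = as.numeric(p$size_class_redundant[sizes]),
               nonredundant = as.numeric(p$size_class_nonredundant[sizes]))
  }))
  utils::write.table(sc, file.path(dir, "size_class.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cx <- do.call(rbind, lapply(report$per_replicate, function(p)
    if (length(p$complexity))
      data.frame(replicate = p$replicate, size = as.integer(names(p$complexity)),
                 complexity = as.numeric(p$complexity)) else NULL))
  utils::write.table(cx, file.path(dir, "complexity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  comp <- do.call(rbind, lapply(report$per_replicate, function(p)
    if (nrow(p$composition))
      data.frame(replicate = p$replicate,
                 position = as.integer(rownames(p$composition)),
                 p$composition) else NULL))
  utils::write.table(comp, file.path(dir, "composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jc <- do.call(rbind, lapply(report$pairs, function(pr)
    data.frame(treatment = pr$treatment, repA = pr$repA, repB = pr$repB,
               jaccard = pr$jaccard, centering_score = pr$centering_score)))
  utils::write.table(jc, file.path(dir, "jaccard.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ma <- do.call(rbind, lapply(report$pairs, function(pr)
    if (nrow(pr$ma)) cbind(repA = pr$repA, repB = pr$repB, pr$ma) else NULL))
  utils::write.table(ma, file.path(dir, "ma_points.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fc <- do.call(rbind, lapply(report$pairs, function(pr)
    if (nrow(pr$fold_change_per_size))
      cbind(repA = pr$repA, repB = pr$repB, pr$fold_change_per_size) else NULL))
  utils::write.table(fc, file.path(dir, "fold_change_per_size.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gm <- do.call(rbind, lapply(report$per_replicate, function(p)
    if (!is.null(p$genome_match_redundant))
      data.frame(replicate = p$replicate,
                 redundant_pct = p$genome_match_redundant$overall,
                 nonredundant_pct = p$genome_match_nonredundant$overall) else NULL))
  if (!is.null(gm))
    utils::write.table(gm, file.path(dir, "genome_match.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$abundance_windows))
    utils::write.table(report$abundance_windows,
                       file.path(dir, "abundance_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  summary <- list(
    normalized_by = report$normalized_by,
    class = report$class,
    top_n = report$top_n,
    totals = lapply(report$per_replicate, function(p)
      list(redundant = p$redundant_total, nonredundant = p$nonredundant_total)),
    jaccard = lapply(report$pairs, function(pr) pr$jaccard),
    centering_scores = lapply(report$pairs, function(pr) pr$centering_score))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
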