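#' Build a read library from a named count vector
#'
#' A read library holds the collapsed reads of one sequencing replicate:
#' a mapping from unique nucleotide sequence to its abundance (number of
#' times it was sequenced). Sequences are upper-cased and U is converted
#' to T, so RNA- and DNA-alphabet inputs collapse together.
#'
#' @param counts Named numeric vector; names are sequences, values are
#'   abundances (>= 1). Duplicate names are summed.
#' @param replicate_id Identifier of the replicate the reads came from.
#' @param size_range Inclusive length window; sequences outside it are
#'   dropped (their total is recorded in the `n_dropped` attribute).
#' @return An object of class `read_library`: a list with elements
#'   `replicate_id` and `counts` (named numeric vector, sequences sorted
#'   lexicographically). Attributes `n_dropped` and `dropped_count` hold
#'   the number of distinct dropped sequences and their summed abundance.
#' @export
read_library <- function(counts, replicate_id = "rep1", size_range = c(15L, 35L)) {
  if (length(counts) == 0L) {
    lib <- structure(list(replicate_id = replicate_id, counts = numeric(0)),
                     class = "read_library")
    attr(lib, "n_dropped") <- 0L
    attr(lib, "dropped_count") <- 0
    return(lib)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of sequence -> abundance")
  seqs <- chartr("uU", "tT", names(counts))
  seqs <- toupper(seqs)
  bad_alpha <- grepl("[^ACGT]", seqs)
  len <- nchar(seqs)
  keep <- !bad_alpha & len >= size_range[1] & len <= size_range[2] & counts > 0
  dropped_count <- sum(counts[!keep])
  n_dropped <- sum(!keep)
  counts <- counts[keep]
  seqs <- seqs[keep]
  if (length(counts)) {
    agg <- tapply(counts, seqs, sum)
    cn <- as.numeric(agg)
    names(cn) <- names(agg)
    cn <- cn[order(names(cn), method = "radix")]
  } else {
    cn <- numeric(0)
  }
  lib <- structure(list(replicate_id = replicate_id, counts = cn),
                   class = "read_library")
  attr(lib, "n_dropped") <- n_dropped
  attr(lib, "dropped_count") <- dropped_count
  lib
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read_library '%s': %d unique sequences, %g total reads\n",
              x$replicate_id, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Total (redundant) read count of a library
#' @param library A `read_library`.
#' @return Sum of abundances over all unique sequences.
#' @export
redundant_total <- function(library) sum(library$counts)

#' Number of unique (non-redundant) sequences of a library
#' @param library A `read_library`.
#' @return Number of distinct sequences.
#' @export
nonredundant_total <- function(library) length(library$counts)

#' Read collapsed small RNA reads from FASTA
#'
#' Two dialects are supported. `plain` treats every FASTA record as one
#' sequenced read; identical sequences are collapsed with summed counts.
#' `count_suffix` is the common collapsed-read convention in which each
#' header carries the read's abundance as an integer after the last `-`
#' or `_` (e.g. `>seq1-534`).
#'
#' U is normalized to T and sequences outside `size_range` are dropped
#' with a tally (attributes `n_dropped`/`dropped_count` of the result).
#'
#' @param path Path to a FASTA file.
#' @param dialect `"plain"` or `"count_suffix"`.
#' @param replicate_id Replicate identifier; defaults to the file name
#'   without extension.
#' @param size_range Inclusive read-length window kept at ingestion.
#' @return A [read_library()].
#' @export
read_fasta_counts <- function(path, dialect = c("plain", "count_suffix"),
                              replicate_id = NULL, size_range = c(15L, 35L)) {
  dialect <- match.arg(dialect)
  if (is.null(replicate_id))
    replicate_id <- tools::file_path_sans_ext(basename(path))
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L)
    return(read_library(numeric(0), replicate_id, size_range))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L)
    return(read_library(numeric(0), replicate_id, size_range))
  seqs <- as.character(set)
  if (dialect == "plain") {
    counts <- rep(1, length(seqs))
  } else {
    hdr <- names(set)
    m <- regmatches(hdr, regexpr("[-_][0-9]+$", hdr))
    ok <- grepl("[-_][0-9]+$", hdr)
    if (any(!ok))
      stop("count_suffix header without parsable count: '", hdr[which(!ok)[1]], "'")
    counts <- as.numeric(sub("^[-_]", "", m))
  }
  names(counts) <- seqs
  read_library(counts, replicate_id, size_range)
}

#' Write a read library as count-suffix FASTA
#'
#' Headers are `>s<index>-<count>` with sequences in lexicographic order,
#' so output is bit-stable for a given library. Re-reading with
#' [read_fasta_counts()] (`dialect = "count_suffix"`) reproduces the
#' library exactly.
#'
#' @param library A `read_library`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta_counts <- function(library, path) {
  seqs <- names(library$counts)
  cnt <- library$counts
  lines <- character(2L * length(seqs))
  if (length(seqs)) {
    lines[c(TRUE, FALSE)] <- sprintf(">s%06d-%d", seq_along(seqs), as.integer(round(cnt)))
    lines[c(FALSE, TRUE)] <- seqs
  }
  writeLines(lines, path)
  invisible(path)
}

#' Define the treatment/replicate hierarchy of an experiment
#'
#' The hierarchy is an ordered list of treatments (e.g. time points),
#' each with one or more replicates. The treatment order is meaningful:
#' the differential-expression caller compares consecutive treatments by
#' default.
#'
#' @param treatments Named list; names are treatment ids (in experimental
#'   order), values are character vectors of replicate ids.
#' @return An object of class `sample_hierarchy`.
#' @export
sample_hierarchy <- function(treatments) {
  if (!is.list(treatments) || is.null(names(treatments)) ||
      any(!nzchar(names(treatments))))
    stop("treatments must be a named list of replicate-id vectors")
  reps <- unlist(treatments, use.names = FALSE)
  if (any(lengths(treatments) < 1L))
    stop("every treatment needs at least one replicate")
  if (anyDuplicated(reps))
    stop("replicate ids must be globally unique; duplicated: ",
         paste(unique(reps[duplicated(reps)]), collapse = ", "))
  structure(list(treatments = treatments), class = "sample_hierarchy")
}

#' @export
print.sample_hierarchy <- function(x, ...) {
  cat("sample_hierarchy:", length(x$treatments), "treatments\n")
  for (t in names(x$treatments))
    cat("  ", t, ": ", paste(x$treatments[[t]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replicate ids of a hierarchy, in order
#' @param hierarchy A `sample_hierarchy`.
#' @return Character vector of replicate ids.
#' @export
hierarchy_replicates <- function(hierarchy)
  unlist(hierarchy$treatments, use.names = FALSE)

#' Treatment of each replicate
#' @param hierarchy A `sample_hierarchy`.
#' @return Named character vector mapping replicate id to treatment id.
#' @export
replicate_treatments <- function(hierarchy) {
  reps <- hierarchy_replicates(hierarchy)
  trt <- rep(names(hierarchy$treatments), lengths(hierarchy$treatments))
  names(trt) <- reps
  trt
}

#' Assemble an expression matrix from per-replicate libraries
#'
#' Rows are the union of all sequences (sorted lexicographically), one
#' column per replicate in hierarchy order. A sequence absent from a
#' replicate has value exactly 0, so raw column sums equal each library's
#' redundant total.
#'
#' @param libraries List of `read_library` objects whose `replicate_id`s
#'   exactly match the hierarchy's replicates.
#' @param hierarchy A [sample_hierarchy()].
#' @return An object of class `expr_matrix`: list with `values` (numeric
#'   matrix, sequences x replicates), `hierarchy`, and `normalized_by`
#'   (empty string for raw counts).
#' @export
build_expression_matrix <- function(libraries, hierarchy) {
  ids <- vapply(libraries, function(l) l$replicate_id, character(1))
  want <- hierarchy_replicates(hierarchy)
  missing <- setdiff(want, ids)
  extra <- setdiff(ids, want)
  if (length(missing) || length(extra))
    stop("replicate mismatch between libraries and hierarchy",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  names(libraries) <- ids
  seqs <- sort(unique(unlist(lapply(libraries, function(l) names(l$counts)),
                             use.names = FALSE)), method = "radix")
  m <- matrix(0, nrow = length(seqs), ncol = length(want),
              dimnames = list(seqs, want))
  for (id in want) {
    cn <- libraries[[id]]$counts
    m[names(cn), id] <- cn
  }
  expr_matrix(m, hierarchy)
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, sequences (rownames) x replicates
#'   (colnames); all values >= 0.
#' @param hierarchy A [sample_hierarchy()] whose replicates equal the
#'   column names.
#' @param normalized_by Tag naming the normalization applied ("" = raw).
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, hierarchy, normalized_by = "") {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must be a matrix with sequence rownames and replicate colnames")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (!setequal(colnames(values), hierarchy_replicates(hierarchy)))
    stop("matrix columns must equal the hierarchy's replicate set")
  values <- values[, hierarchy_replicates(hierarchy), drop = FALSE]
  structure(list(values = values, hierarchy = hierarchy,
                 normalized_by = normalized_by),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d sequences x %d replicates (%s)\n",
              nrow(x$values), ncol(x$values),
              if (nzchar(x$normalized_by)) x$normalized_by else "raw"))
  invisible(x)
}

#' Extract one replicate column of an expression matrix as a library
#' @param matrix An `expr_matrix`.
#' @param replicate_id Column to extract.
#' @return A `read_library` with the column's nonzero values.
#' @export
matrix_column_library <- function(matrix, replicate_id) {
  v <- matrix$values[, replicate_id]
  v <- v[v > 0]
  structure(list(replicate_id = replicate_id, counts = v),
            class = "read_library")
}

#' Drop replicates and/or size classes from an expression matrix
#'
#' Used to exclude problematic replicates flagged during quality checking
#' (a treatment whose replicates are all dropped is removed from the
#' hierarchy) and to restrict the analysis to a read-length window. All
#' remaining values are unchanged.
#'
#' @param matrix An `expr_matrix`.
#' @param drop_replicates Character vector of replicate ids to remove.
#' @param size_range Inclusive length interval `c(lo, hi)` of sequences
#'   to keep.
#' @return A filtered `expr_matrix`.
#' @export
filter_matrix <- function(matrix, drop_replicates = character(0),
                          size_range = c(15L, 35L)) {
  if (length(size_range) != 2L || size_range[1] > size_range[2])
    stop("size_range must be a non-empty inclusive interval c(lo, hi)")
  unknown <- setdiff(drop_replicates, colnames(matrix$values))
  if (length(unknown))
    stop("unknown replicate(s) to drop: ", paste(unknown, collapse = ", "))
  trts <- lapply(matrix$hierarchy$treatments, setdiff, y = drop_replicates)
  trts <- trts[lengths(trts) > 0L]
  if (!length(trts)) stop("filtering removed every replicate")
  hier <- sample_hierarchy(trts)
  keep_cols <- hierarchy_replicates(hier)
  len <- nchar(rownames(matrix$values))
  keep_rows <- len >= size_range[1] & len <= size_range[2]
  expr_matrix(matrix$values[keep_rows, keep_cols, drop = FALSE], hier,
              matrix$normalized_by)
}

#' Write an expression matrix as TSV
#'
#' First column `sequence`, then one column per replicate (hierarchy
#' order). Rows are in lexicographic sequence order, so the output is
#' bit-stable.
#'
#' @param matrix An `expr_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  v <- matrix$values[order(rownames(matrix$values), method = "radix"), ,
                     drop = FALSE]
  df <- data.frame(sequence = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @param hierarchy The experiment's [sample_hierarchy()].
#' @param normalized_by Normalization tag to attach.
#' @return An `expr_matrix`.
#' @export
read_matrix_tsv <- function(path, hierarchy, normalized_by = "") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sequence
  expr_matrix(m, hierarchy, normalized_by)
}

#' Write a read library as TSV (sequence, count)
#' @param library A `read_library`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_library_tsv <- function(library, path) {
  df <- data.frame(sequence = names(library$counts),
                   count = unname(library$counts))
  df <- df[order(df$sequence, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
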