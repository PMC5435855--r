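#' Confidence interval over replicate expression levels
#'
#' With exactly two replicates the maximal expression interval
#' `[min, max]` is used; with three or more, Chebyshev's interval
#' `[mean - k*sd, mean + k*sd]` (sample sd), floored at 0 since
#' abundances cannot be negative. Chebyshev's inequality guarantees
#' distribution-free coverage of at least `1 - 1/k^2` (75% at the
#' default `k = 2`).
#'
#' @param values Numeric vector of replicate abundances (>= 2 values,
#'   all >= 0).
#' @param k Chebyshev multiplier.
#' @param method `"auto"` (min-max for 2 replicates, Chebyshev
#'   otherwise), `"chebyshev"` or `"minmax"`.
#' @return List of class `conf_interval` with `lo`, `hi`, `method`.
#' @export
confidence_interval <- function(values, k = 2,
                                method = c("auto", "chebyshev", "minmax")) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need at least 2 replicate values")
  if (any(values < 0)) stop("abundances must be non-negative")
  if (method == "auto") method <- if (length(values) == 2L) "minmax" else "chebyshev"
  if (method == "minmax") {
    ci <- list(lo = min(values), hi = max(values), method = "minmax")
  } else {
    m <- mean(values); s <- stats::sd(values)
    ci <- list(lo = max(0, m - k * s), hi = m + k * s, method = "chebyshev")
  }
  class(ci) <- "conf_interval"
  ci
}

#' Directional comparison of two confidence intervals
#'
#' `S` (straight) when the closed intervals intersect (touching
#' endpoints count as overlap, avoiding knife-edge calls), `U` (up) when
#' the observed interval lies entirely above the reference, `D` (down)
#' when entirely below. Exactly one outcome applies.
#'
#' @param reference,observed `conf_interval` objects (or lists with
#'   `lo`/`hi`).
#' @return `"U"`, `"D"` or `"S"`.
#' @export
compare_intervals <- function(reference, observed) {
  if (observed$lo > reference$hi) "U"
  else if (observed$hi < reference$lo) "D"
  else "S"
}

#' Log2 offset fold change (LOFC)
#'
#' `log2((observed + offset) / (reference + offset))`. The additive
#' offset, estimated from the data's strand-bias noise profile (see
#' [estimate_offset()]), damps fold changes between low-abundance
#' values so that the DE ranking is not flooded by noise-level ratios.
#'
#' @param observed,reference Non-negative expression values (for U
#'   calls the proximal ends are `observed$lo` vs `reference$hi`; for D,
#'   `observed$hi` vs `reference$lo`).
#' @param offset Positive noise offset.
#' @return Signed log2 offset fold change;
#'   `lofc(a, b, o) == -lofc(b, a, o)`.
#' @export
lofc <- function(observed, reference, offset) {
  if (offset <= 0) stop("offset must be > 0")
  log2((observed + offset) / (reference + offset))
}

#' Call the U/D/S descriptor and LOFC amplitude for one comparison
#'
#' Combines [compare_intervals()] with the amplitude rule: a
#' provisional U or D is demoted to S when the |LOFC| computed on the
#' proximate extremes (the closest ends of the two intervals) is below
#' `threshold`. An LOFC of 1 corresponds to a two-fold change, the
#' smallest difference typically confirmable by Northern blot or qPCR.
#' For S outcomes an informational LOFC of the interval midpoints is
#' reported; it never participates in calling or ranking.
#'
#' @param reference,observed `conf_interval` objects.
#' @param offset Positive noise offset.
#' @param threshold Minimum |LOFC| for a U/D call (default 1).
#' @return List with `descriptor` (`"U"`, `"D"` or `"S"`) and `lofc`.
#' @export
call_descriptor <- function(reference, observed, offset, threshold = 1) {
  dir <- compare_intervals(reference, observed)
  if (dir == "U") {
    l <- lofc(observed$lo, reference$hi, offset)
    if (abs(l) < threshold) dir <- "S"
  } else if (dir == "D") {
    l <- lofc(observed$hi, reference$lo, offset)
    if (abs(l) < threshold) dir <- "S"
  } else {
    l <- lofc((observed$lo + observed$hi) / 2,
              (reference$lo + reference$hi) / 2, offset)
  }
  list(descriptor = dir, lofc = l)
}

treatment_cis <- function(matrix, k, ci_method) {
  trts <- matrix$hierarchy$treatments
  lapply(trts, function(reps) {
    v <- matrix$values[, reps, drop = FALSE]
    n <- ncol(v)
    meth <- ci_method
    if (meth == "auto") meth <- if (n == 2L) "minmax" else "chebyshev"
    if (n < 2L)
      stop("every treatment needs >= 2 replicates for a confidence interval")
    if (meth == "minmax") {
      lo <- do.call(pmin, as.data.frame(v))
      hi <- do.call(pmax, as.data.frame(v))
    } else {
      m <- rowMeans(v)
      s <- sqrt(rowSums((v - m)^2) / (n - 1))
      lo <- pmax(0, m - k * s)
      hi <- m + k * s
    }
    list(lo = lo, hi = hi, method = meth)
  })
}

#' Confidence-interval differential expression call
#'
#' For every sequence a confidence interval is computed per treatment
#' ([confidence_interval()] semantics, vectorized), then each
#' comparison — consecutive treatment pairs in hierarchy order by
#' default, or every treatment against a named reference — is assigned
#' a U/D/S descriptor and LOFC ([call_descriptor()]). The descriptors
#' concatenate into a pattern string (e.g. `"US"`); `de_flag` marks
#' sequences with any U or D. Rows are sorted by the maximum |LOFC|
#' over U/D comparisons (descending), so the ranking is not populated
#' by high but insignificant fold changes; all-S sequences rank last.
#'
#' @param matrix A normalized [expr_matrix()] with >= 2 treatments.
#' @param offset Positive noise offset (see [estimate_offset()]).
#' @param threshold Minimum |LOFC| for a U/D call (default 1).
#' @param scheme `"consecutive"` or `"vs_reference"`.
#' @param reference Reference treatment id (for `"vs_reference"`).
#' @param ci_method,k Passed to the interval construction.
#' @return data.frame of class `de_call`: `sequence`, `<trt>_lo` /
#'   `<trt>_hi` per treatment, `desc_<ref>_vs_<obs>` and
#'   `lofc_<ref>_vs_<obs>` per comparison, `pattern`, `de_flag`,
#'   `rank_lofc`. Attribute `comparisons` lists the (reference,
#'   observed) pairs.
#' @export
call_de <- function(matrix, offset, threshold = 1,
                    scheme = c("consecutive", "vs_reference"),
                    reference = NULL, ci_method = c("auto", "chebyshev", "minmax"),
                    k = 2) {
  scheme <- match.arg(scheme)
  ci_method <- match.arg(ci_method)
  trts <- names(matrix$hierarchy$treatments)
  if (length(trts) < 2L) stop("need at least 2 treatments")
  if (scheme == "consecutive") {
    comps <- data.frame(reference = trts[-length(trts)], observed = trts[-1])
  } else {
    if (is.null(reference) || !reference %in% trts)
      stop("unknown reference treatment: ", reference)
    obs <- setdiff(trts, reference)
    comps <- data.frame(reference = reference, observed = obs)
  }
  cis <- treatment_cis(matrix, k, ci_method)
  seqs <- rownames(matrix$values)
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (t in trts) {
    out[[paste0(t, "_lo")]] <- cis[[t]]$lo
    out[[paste0(t, "_hi")]] <- cis[[t]]$hi
  }
  desc_mat <- matrix("", nrow = length(seqs), ncol = nrow(comps))
  lofc_mat <- matrix(0, nrow = length(seqs), ncol = nrow(comps))
  for (ci_i in seq_len(nrow(comps))) {
    r <- cis[[comps$reference[ci_i]]]
    o <- cis[[comps$observed[ci_i]]]
    up <- o$lo > r$hi
    down <- o$hi < r$lo
    l <- ifelse(up, lofc(o$lo, r$hi, offset),
         ifelse(down, lofc(o$hi, r$lo, offset),
                lofc((o$lo + o$hi) / 2, (r$lo + r$hi) / 2, offset)))
    d <- ifelse(up & abs(l) >= threshold, "U",
         ifelse(down & abs(l) >= threshold, "D", "S"))
    desc_mat[, ci_i] <- d
    lofc_mat[, ci_i] <- l
    tag <- paste0(comps$reference[ci_i], "_vs_", comps$observed[ci_i])
    out[[paste0("desc_", tag)]] <- d
    out[[paste0("lofc_", tag)]] <- l
  }
  out$pattern <- apply(desc_mat, 1, paste, collapse = "")
  out$de_flag <- grepl("[UD]", out$pattern)
  sig <- abs(lofc_mat)
  sig[desc_mat == "S"] <- -Inf
  out$rank_lofc <- apply(sig, 1, max)
  out <- out[order(-out$rank_lofc, out$sequence, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "comparisons") <- comps
  attr(out, "offset") <- offset
  attr(out, "threshold") <- threshold
  class(out) <- c("de_call", "data.frame")
  out
}

#' Group DE calls by expression pattern
#'
#' Sequences sharing the same pattern string form a cluster. The
#' headline report keeps clusters with more than `min_size` members and
#' (by default) drops the all-S cluster, since the vast majority of
#' reads are not expected to be differentially expressed; the full
#' partition is always returned.
#'
#' @param calls A [call_de()] result.
#' @param min_size Clusters with `<= min_size` members are suppressed
#'   from the headline report (default 15).
#' @param drop_all_s Drop the all-S pattern from the headline report.
#' @return List with `full` (named list pattern -> sequences, a
#'   partition of all sequences) and `headline` (the filtered subset).
#' @export
cluster_patterns <- function(calls, min_size = 15L, drop_all_s = TRUE) {
  full <- split(calls$sequence, calls$pattern)
  headline <- full[lengths(full) > min_size]
  if (drop_all_s && length(headline)) {
    all_s <- strrep("S", nchar(names(headline)))
    headline <- headline[names(headline) != all_s]
  }
  list(full = full, headline = headline)
}

#' Write DE calls and pattern clusters to TSV
#'
#' Writes `de_calls.tsv` (one row per sequence with per-treatment
#' interval bounds, per-comparison descriptors and LOFCs, pattern and
#' ranking key) and `clusters.tsv` (pattern, size, in_headline).
#'
#' @param calls A [call_de()] result.
#' @param dir Output directory.
#' @param min_size,drop_all_s Passed to [cluster_patterns()].
#' @return Invisibly, `dir`.
#' @export
write_de_calls <- function(calls, dir, min_size = 15L, drop_all_s = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(calls)
  df$rank_lofc[!is.finite(df$rank_lofc)] <- NA
  utils::write.table(df, file.path(dir, "de_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- cluster_patterns(calls, min_size, drop_all_s)
  cdf <- data.frame(pattern = names(cl$full), size = lengths(cl$full),
                    in_headline = names(cl$full) %in% names(cl$headline))
  cdf <- cdf[order(-cdf$size, cdf$pattern), ]
  utils::write.table(cdf, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
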