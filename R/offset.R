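#' Strand-resolved abundance profiles of genome windows
#'
#' The genome is tiled from position 0 into non-overlapping windows of
#' `window_len` nt. Each genomic hit of a read contributes
#' `count / number-of-hits` (so multi-mapped reads conserve library
#' totals) to the strand-specific abundance of the window containing its
#' 5'-most genomic coordinate (the start for plus-strand hits, the end
#' for minus-strand hits). Windows with zero abundance are excluded.
#'
#' @param alignments An [alignment_set()].
#' @param library The matching [read_library()] supplying abundances.
#' @param window_len Window length in nt (>= 50; default 1000).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `plus`, `minus`, `total` and `bias`
#'   (`plus / total`, in \[0, 1\]).
#' @export
window_profiles <- function(alignments, library, window_len = 1000L) {
  if (window_len < 50) stop("window_len must be >= 50")
  hits <- alignments$hits
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), plus = numeric(0), minus = numeric(0),
                      total = numeric(0), bias = numeric(0))
  if (!nrow(hits)) return(empty)
  nh <- hit_counts(alignments)
  cnt <- library$counts[hits$sequence]
  if (anyNA(cnt)) stop("alignment set contains sequences absent from the library")
  w <- cnt / nh[hits$sequence]
  five_prime <- ifelse(hits$strand == "+", hits$start,
                       hits$start + nchar(hits$sequence) - 1L)
  win <- floor(five_prime / window_len)
  key <- paste(hits$chrom, win, sep = "\r")
  plus <- tapply(w * (hits$strand == "+"), key, sum)
  minus <- tapply(w * (hits$strand == "-"), key, sum)
  parts <- strsplit(names(plus), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  wk <- as.numeric(vapply(parts, `[`, character(1), 2L))
  glen <- alignments$genome_lengths[chrom]
  out <- data.frame(chrom = chrom, start = wk * window_len,
                    end = pmin((wk + 1) * window_len, as.numeric(glen)),
                    plus = as.numeric(plus), minus = as.numeric(minus))
  out$total <- out$plus + out$minus
  out <- out[out$total > 0, ]
  out$bias <- out$plus / out$total
  out <- out[order(out$chrom, out$start, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Kullback-Leibler divergence of a histogram from the uniform
#'
#' `KL(p || U_B) = sum over occupied bins of p_i * log2(p_i * B)`,
#' in bits. Zero iff `p` is uniform.
#'
#' @param histogram Probability vector over `B >= 2` bins (sums to 1).
#' @return Non-negative divergence in bits.
#' @export
kl_divergence <- function(histogram) {
  if (length(histogram) < 2L) stop("need at least 2 bins")
  if (any(histogram < 0)) stop("histogram must be non-negative")
  if (abs(sum(histogram) - 1) > 1e-8)
    stop("histogram must sum to 1 (got ", sum(histogram), ")")
  B <- length(histogram)
  p <- histogram[histogram > 0]
  sum(p * log2(p * B))
}

#' Raw KL divergence curve over abundance levels
#'
#' Windows are sorted by total abundance and grouped into consecutive
#' abundance levels of at least `min_windows_per_level` windows each
#' (the last level absorbs the remainder), so each level has enough
#' windows for a stable strand-bias histogram. Per level, strand biases
#' are binned into `n_bias_bins` equal bins on \[0, 1\] and the KL
#' divergence of the normalized histogram from the uniform is computed;
#' the level's abundance coordinate is the median window total.
#'
#' @param windows Output of [window_profiles()].
#' @param n_bias_bins Number of strand-bias bins (default 100; beyond
#'   the number of distinct observed biases the curve no longer
#'   changes).
#' @param min_windows_per_level Minimum windows per abundance level.
#' @return data.frame with columns `level`, `abundance` (non-decreasing),
#'   `raw_kl`, `n_windows`.
#' @export
kl_curve <- function(windows, n_bias_bins = 100L,
                     min_windows_per_level = 100L) {
  n <- nrow(windows)
  if (n < 2L * min_windows_per_level)
    stop("need at least ", 2L * min_windows_per_level,
         " windows with nonzero abundance (got ", n, ")")
  # secondary sort on bias makes level membership deterministic when
  # window totals tie, so the curve is invariant to input order
  ord <- order(windows$total, windows$bias)
  total <- windows$total[ord]
  bias <- windows$bias[ord]
  n_levels <- n %/% min_windows_per_level
  sizes <- rep(min_windows_per_level, n_levels)
  sizes[n_levels] <- sizes[n_levels] + n %% min_windows_per_level
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  out <- lapply(seq_len(n_levels), function(l) {
    i <- starts[l]:stops[l]
    bin <- pmin(floor(bias[i] * n_bias_bins) + 1L, n_bias_bins)
    p <- tabulate(bin, nbins = n_bias_bins) / length(i)
    data.frame(level = l, abundance = stats::median(total[i]),
               raw_kl = kl_divergence(p), n_windows = length(i))
  })
  do.call(rbind, out)
}

#' LOESS smoothing (local linear regression, tricube weights)
#'
#' Degree-1 local regression with tricube kernel over the nearest
#' `span * n` points, evaluated at the input abscissae. Constants and
#' exact lines are reproduced exactly.
#'
#' @param x,y Numeric vectors (>= 5 points; `x` not all equal).
#' @param span Smoothing span in (0, 1\].
#' @return Numeric vector of smoothed values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5L) stop("need at least 5 points to smooth")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (length(unique(x)) == 1L) stop("degenerate x: all values equal")
  # a local linear fit needs >= 3 points in every neighborhood; widen the
  # effective span accordingly for short series
  span <- max(span, 3 / length(x))
  fit <- suppressWarnings(
    stats::loess(y ~ x, data = data.frame(x = x, y = y), span = span,
                 degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  suppressWarnings(as.numeric(stats::predict(fit, newdata = data.frame(x = x))))
}

#' Estimate the noise-to-signal offset from strand-bias KL curves
#'
#' Low-abundance genomic windows are dominated by degradation noise
#' with no preferred strand, while genuine sRNA loci above the noise
#' range are strand biased; the divergence of the strand-bias
#' distribution from uniform is therefore high at very low abundance
#' (few incident reads), dips across the noise-to-signal boundary and
#' rises again for genuine loci. Per sample, the offset is the
#' abundance coordinate of the global minimum of the LOESS-smoothed KL
#' curve (ties resolved to the smallest abundance); the dataset offset
#' is the minimum over samples.
#'
#' @param windows_by_sample Named list of [window_profiles()] outputs,
#'   one per sample (typically per replicate).
#' @param n_bias_bins,min_windows_per_level Passed to [kl_curve()].
#' @param span LOESS span (default 0.3).
#' @return List of class `offset_estimate` with `per_sample`
#'   (data.frame: sample, offset), `curves` (data.frame: sample, level,
#'   abundance, raw_kl, smoothed_kl) and `dataset_offset`.
#' @export
estimate_offset <- function(windows_by_sample, n_bias_bins = 100L,
                            min_windows_per_level = 100L, span = 0.3) {
  if (is.data.frame(windows_by_sample))
    windows_by_sample <- list(sample = windows_by_sample)
  if (is.null(names(windows_by_sample)))
    names(windows_by_sample) <- paste0("sample", seq_along(windows_by_sample))
  curves <- list()
  offsets <- numeric(0)
  for (s in names(windows_by_sample)) {
    cur <- kl_curve(windows_by_sample[[s]], n_bias_bins, min_windows_per_level)
    cur$smoothed_kl <- loess_smooth(cur$abundance, cur$raw_kl, span)
    best <- which(cur$smoothed_kl == min(cur$smoothed_kl))
    offsets[s] <- min(cur$abundance[best])
    curves[[s]] <- cbind(sample = s, cur)
  }
  structure(list(per_sample = data.frame(sample = names(offsets),
                                         offset = unname(offsets)),
                 curves = do.call(rbind, curves),
                 dataset_offset = min(offsets)),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat("offset_estimate: dataset offset", x$dataset_offset, "\n")
  print(x$per_sample)
  invisible(x)
}

#' Per-sample window profiles for a whole experiment
#'
#' Convenience wrapper: builds [window_profiles()] for each replicate
#' column of an expression matrix against a shared alignment set.
#'
#' @param matrix An [expr_matrix()] (raw counts are appropriate).
#' @param alignments [alignment_set()] covering the matrix's sequences.
#' @param window_len Window length in nt.
#' @return Named list of window data frames, one per replicate.
#' @export
experiment_window_profiles <- function(matrix, alignments,
                                       window_len = 1000L) {
  reps <- colnames(matrix$values)
  out <- lapply(reps, function(r)
    window_profiles(alignments, matrix_column_library(matrix, r), window_len))
  names(out) <- reps
  out
}

#' Write an offset estimate to TSV + JSON
#'
#' Writes `kl_curve.tsv` (sample, level, abundance, raw_kl, smoothed_kl,
#' n_windows) and `offsets.json` (per-sample offsets and the dataset
#' offset).
#'
#' @param estimate An [estimate_offset()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_offset_estimate <- function(estimate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(estimate$curves, file.path(dir, "kl_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(per_sample = stats::setNames(as.list(estimate$per_sample$offset),
                                      estimate$per_sample$sample),
         dataset_offset = estimate$dataset_offset),
    file.path(dir, "offsets.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
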