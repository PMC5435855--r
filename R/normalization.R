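new_normalization_result <- function(values, matrix, method, factors = NULL,
                                     details = NULL) {
  res <- list(matrix = expr_matrix(values, matrix$hierarchy, method),
              method = method, factors = factors, details = details)
  class(res) <- "normalization_result"
  res
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("normalization_result:", x$method, "\n")
  if (!is.null(x$factors)) {
    cat("  factors:\n")
    print(round(x$factors, 4))
  }
  invisible(x)
}

resolve_total <- function(colsums, total) {
  if (is.numeric(total)) return(total)
  switch(match.arg(total, c("average", "median")),
         average = mean(colsums), median = stats::median(colsums))
}

#' Total-count (RPM / reads-per-total) normalization
#'
#' Scales every column to a common total `T`: `value' = value * T /
#' colsum`. The classic RPM choice `T = 1e6` can distort fold changes
#' when `T` is far from the actual library sizes (scaling 10 M-read
#' libraries down to 1 M shrinks all expression tenfold and can hide
#' differential expression), so the default `T` is the mean of the
#' column sums; `"median"` or a fixed number may be given instead.
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param total `"average"`, `"median"`, or a fixed numeric total.
#' @return A `normalization_result`; `factors` holds the per-replicate
#'   scale factors `T / colsum`.
#' @export
normalize_total_count <- function(matrix, total = "average") {
  cs <- colSums(matrix$values)
  if (any(cs == 0))
    stop("zero column sum in replicate(s): ",
         paste(colnames(matrix$values)[cs == 0], collapse = ", "))
  T <- resolve_total(cs, total)
  f <- T / cs
  new_normalization_result(sweep(matrix$values, 2, f, "*"), matrix,
                           "total_count", f)
}

nonzero_upper_quartile <- function(x) {
  nz <- x[x > 0]
  if (length(nz) < 4L) stop("need at least 4 nonzero values per column")
  stats::quantile(nz, 0.75, type = 7, names = FALSE)
}

#' Upper-quartile normalization
#'
#' Scales columns by the 75th percentile of their nonzero values
#' (sRNA matrices are zero-dominated, so the quartile of the full column
#' would often be 0): `value' = value * T / UQ`, with `T` the mean of
#' the per-column upper quartiles by default.
#'
#' @param matrix An [expr_matrix()].
#' @param total `"average"`, `"median"` (of the upper quartiles), or a
#'   fixed numeric total.
#' @return A `normalization_result`; `factors` holds the per-replicate
#'   upper quartiles.
#' @export
normalize_upper_quartile <- function(matrix, total = "average") {
  uq <- apply(matrix$values, 2, nonzero_upper_quartile)
  T <- resolve_total(uq, total)
  new_normalization_result(sweep(matrix$values, 2, T / uq, "*"), matrix,
                           "upper_quartile", uq)
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' The canonical TMM scheme: for each column, M (log2 ratio) and A (log2
#' mean) values are computed against a reference column on the
#' library-size-scaled proportions of sequences nonzero in both; the
#' most extreme `trim_m` of M values and `trim_a` of A values are
#' trimmed on each side; the scale factor is 2 to the precision-weighted
#' mean of the surviving M values. Factors are rescaled to geometric
#' mean 1 (so their product is 1), and normalized values are
#' `value / (factor * colsum) * T`.
#'
#' @param matrix An [expr_matrix()].
#' @param reference Reference column id, or `"auto"` (column whose
#'   nonzero upper quartile is closest to the mean of those quartiles).
#' @param trim_m,trim_a Two-sided trim fractions for M and A (canonical
#'   defaults 0.30 and 0.05).
#' @param total Normalization total `T` (see
#'   [normalize_total_count()]).
#' @return A `normalization_result`; `factors` holds the rescaled TMM
#'   factors.
#' @export
normalize_tmm <- function(matrix, reference = "auto", trim_m = 0.30,
                          trim_a = 0.05, total = "average") {
  v <- matrix$values
  cs <- colSums(v)
  if (reference == "auto") {
    uq <- apply(v, 2, nonzero_upper_quartile) / cs
    reference <- colnames(v)[which.min(abs(uq - mean(uq)))]
  }
  if (!reference %in% colnames(v)) stop("unknown reference column: ", reference)
  ref <- v[, reference]
  f <- vapply(colnames(v), function(id) {
    if (id == reference) return(1)
    obs <- v[, id]
    keep <- obs > 0 & ref > 0
    yo <- obs[keep]; yr <- ref[keep]
    no <- cs[[id]]; nr <- cs[[reference]]
    M <- log2((yo / no) / (yr / nr))
    A <- 0.5 * log2((yo / no) * (yr / nr))
    w <- (no - yo) / (no * yo) + (nr - yr) / (nr * yr)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep2) < 10L) {
      warning("fewer than 10 sequences survive TMM trimming for '", id,
              "'; falling back to untrimmed mean of M")
      return(2^mean(M))
    }
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  T <- resolve_total(cs, total)
  vals <- sweep(v, 2, f * cs, "/") * T
  new_normalization_result(vals, matrix, "tmm", f,
                           details = list(reference = reference))
}

#' Median-of-ratios (DESeq-style) size-factor normalization
#'
#' The size factor of each column is the median, over sequences nonzero
#' in every column, of the value divided by that sequence's geometric
#' mean across columns; normalized values are `value / factor`.
#'
#' @param matrix An [expr_matrix()].
#' @return A `normalization_result`; `factors` holds the size factors.
#' @export
normalize_deseq <- function(matrix) {
  v <- matrix$values
  all_nz <- rowSums(v == 0) == 0
  if (!any(all_nz))
    stop("no sequence is nonzero in all columns; consider filtering to a ",
         "smaller size range or dropping sparse replicates first")
  lv <- log(v[all_nz, , drop = FALSE])
  loggeo <- rowMeans(lv)
  f <- apply(lv, 2, function(col) exp(stats::median(col - loggeo)))
  new_normalization_result(sweep(v, 2, f, "/"), matrix, "deseq", f)
}

#' Rank-based quantile normalization adapted for sRNA counts
#'
#' Classic quantile normalization imposes a common distribution by rank,
#' with two adaptations for sequencing counts: (i) reads that tie on
#' abundance within a sample receive the same normalized abundance,
#' namely the average of the reference values at their ranks; (ii) a
#' read absent from a sample (abundance 0) stays exactly 0 after
#' normalization. The reference distribution is the rank-wise mean of
#' the sorted columns (zeros included at the bottom).
#'
#' @param matrix An [expr_matrix()] with at least 2 columns.
#' @return A `normalization_result` (no scale factors).
#' @export
normalize_quantile_adapted <- function(matrix) {
  v <- matrix$values
  if (ncol(v) < 2L) stop("quantile normalization needs at least 2 columns")
  sorted <- apply(v, 2, sort)
  ref <- rowMeans(sorted)
  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    ord <- order(x)
    assigned <- numeric(length(x))
    assigned[ord] <- ref
    # ties: average the reference values the tied group spans
    tied <- ave(assigned, x, FUN = mean)
    tied[x == 0] <- 0
    out[, j] <- tied
  }
  new_normalization_result(out, matrix, "quantile_adapted")
}

# multivariate hypergeometric draw: sample k reads without replacement
# from a library given as a vector of per-sequence counts
rmhyper <- function(counts, k) {
  total <- sum(counts)
  if (k > total) stop("cannot subsample ", k, " reads from ", total)
  idx <- sample.int(total, k)
  breaks <- c(0, cumsum(counts))
  tabulate(findInterval(idx - 0.5, breaks), nbins = length(counts))
}

ks_stat <- function(x, y) {
  # two-sample Kolmogorov-Smirnov statistic, ties allowed
  all <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(all)
  Fy <- stats::ecdf(y)(all)
  max(abs(Fx - Fy))
}

#' Subsampling normalization to the minimum library size
#'
#' Reads of every column are sampled without replacement down to the
#' minimum column total, in two steps. (i) Consistency scan: each column
#' is subsampled at decreasing proportions (grid step 0.1) of its total
#' and the nonzero abundance distribution of each subsample is compared
#' to the original with a two-sample Kolmogorov-Smirnov test; the scan
#' stops early (and is reported) if the distribution changes
#' significantly (`p < alpha`) before the target size is reached.
#' (ii) Bootstrap: `n_boot` subsamples are drawn at the target size;
#' their pairwise KS distances measure subsample variability (flagged
#' high when the median pairwise distance exceeds the 95th percentile of
#' the subsample-to-original distances), and the medoid subsample
#' (minimum summed distance to the others) is returned as the
#' representative, i.e. non-outlier, draw.
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param seed Integer seed; the procedure is bit-reproducible given the
#'   seed.
#' @param n_boot Number of bootstrap subsamples per column.
#' @param alpha Significance level of the KS consistency scan.
#' @return A `normalization_result`; `details` reports per column the
#'   scan outcome, the variability flag, and the distances.
#' @export
normalize_subsampling <- function(matrix, seed = 1L, n_boot = 100L,
                                  alpha = 0.05) {
  v <- matrix$values
  cs <- colSums(v)
  target <- min(cs)
  if (target <= 0) stop("minimum library size is 0; nothing to subsample to")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- v
  details <- list()
  for (j in seq_len(ncol(v))) {
    counts <- v[, j]
    orig_nz <- counts[counts > 0]
    scan_stop <- NA_real_
    props <- seq(0.9, 0.1, by = -0.1)
    props <- props[props * cs[j] > target]
    for (p in props) {
      sub <- rmhyper(counts, round(p * cs[j]))
      pv <- suppressWarnings(
        stats::ks.test(sub[sub > 0], orig_nz, exact = FALSE)$p.value)
      if (pv < alpha) { scan_stop <- p; break }
    }
    boots <- replicate(n_boot, rmhyper(counts, target))
    d <- matrix(0, n_boot, n_boot)
    nzlist <- lapply(seq_len(n_boot), function(b) boots[boots[, b] > 0, b])
    for (a in seq_len(n_boot - 1L))
      for (b in seq(a + 1L, n_boot))
        d[a, b] <- d[b, a] <- ks_stat(nzlist[[a]], nzlist[[b]])
    d_orig <- vapply(nzlist, ks_stat, numeric(1), y = orig_nz)
    high_var <- stats::median(d[upper.tri(d)]) >
      stats::quantile(d_orig, 0.95, type = 7, names = FALSE)
    medoid <- which.min(rowSums(d))
    out[, j] <- boots[, medoid]
    details[[colnames(v)[j]]] <- list(
      scan_stopped_at_proportion = scan_stop, high_variability = high_var,
      median_pairwise_distance = stats::median(d[upper.tri(d)]),
      medoid = medoid)
  }
  new_normalization_result(out, matrix, "subsampling",
                           factors = cs / target, details = details)
}

normalization_methods <- c("total_count", "upper_quartile", "tmm", "deseq",
                           "quantile_adapted", "subsampling")

#' Apply a normalization method by name
#'
#' @param matrix An [expr_matrix()].
#' @param method One of `"total_count"`, `"upper_quartile"`, `"tmm"`,
#'   `"deseq"`, `"quantile_adapted"`, `"subsampling"`, or `"raw"` (no
#'   normalization).
#' @param ... Passed to the specific method.
#' @return A `normalization_result`.
#' @export
normalize_matrix <- function(matrix, method, ...) {
  switch(match.arg(method, c(normalization_methods, "raw")),
         total_count = normalize_total_count(matrix, ...),
         upper_quartile = normalize_upper_quartile(matrix, ...),
         tmm = normalize_tmm(matrix, ...),
         deseq = normalize_deseq(matrix, ...),
         quantile_adapted = normalize_quantile_adapted(matrix, ...),
         subsampling = normalize_subsampling(matrix, ...),
         raw = new_normalization_result(matrix$values, matrix, "raw"))
}

#' Replicate-based evaluation of normalization methods
#'
#' For each candidate method, the between-replicate log2 fold-change
#' quartiles are computed per treatment and size class on the normalized
#' matrix. Under the assumption that replicates carry no true
#' differential expression, a suitable normalization brings every
#' distribution onto the 0 line; methods are ranked by their centering
#' score (maximum over replicate pairs and size classes of |median M|,
#' zero-pairs excluded as in [ma_values()]).
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param methods Character vector of method names (see
#'   [normalize_matrix()]); `"raw"` may be included as baseline.
#' @param ... Passed through to the methods (e.g. `seed` for
#'   subsampling).
#' @return List with `evaluation` (data.frame: method, treatment, repA,
#'   repB, size, n, q1, median, q3), `centering_scores` (named vector)
#'   and `ranking` (method names, best first).
#' @export
evaluate_normalizations <- function(matrix, methods = normalization_methods,
                                    ...) {
  rows <- list()
  scores <- stats::setNames(numeric(length(methods)), methods)
  for (m in methods) {
    res <- normalize_matrix(matrix, m, ...)
    nm <- res$matrix
    worst <- 0
    for (trt in names(nm$hierarchy$treatments)) {
      rr <- nm$hierarchy$treatments[[trt]]
      if (length(rr) < 2L) next
      cmb <- utils::combn(rr, 2L)
      for (jj in seq_len(ncol(cmb))) {
        a <- matrix_column_library(nm, cmb[1, jj])
        b <- matrix_column_library(nm, cmb[2, jj])
        fc <- fold_change_distribution_per_size(a, b)
        if (nrow(fc))
          rows[[length(rows) + 1L]] <-
            cbind(method = m, treatment = trt,
                  repA = cmb[1, jj], repB = cmb[2, jj], fc)
        csc <- attr(fc, "centering_score")
        if (is.finite(csc)) worst <- max(worst, csc)
      }
    }
    scores[m] <- worst
  }
  evaluation <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0))
  rownames(evaluation) <- NULL
  list(evaluation = evaluation, centering_scores = scores,
       ranking = names(sort(scores)))
}
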