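test_that("total-count normalization scales columns to the common total", {
  v <- matrix(c(10, 30, 20, 60), 2,
              dimnames = list(rand_seq(2, 21), c("a", "b")))
  m <- expr_matrix(v, sample_hierarchy(list(T = c("a", "b"))))
  r <- normalize_total_count(m, total = 1e6)
  expect_equal(unname(r$matrix$values[, "a"]), c(250000, 750000))
  expect_equal(unname(colSums(r$matrix$values)), c(1e6, 1e6))
  # T = colsum is the identity for that column
  r2 <- normalize_total_count(m, total = 40)
  expect_equal(r2$matrix$values[, "a"], v[, "a"])
  # scaling 10M-read columns at 1M shrinks everything tenfold
  v3 <- v * 1e6 / colSums(v)[col(v)] * 10   # columns each sum to 10M
  m3 <- expr_matrix(v3, m$hierarchy)
  r3 <- normalize_total_count(m3, total = 1e6)
  expect_equal(r3$matrix$values, v3 * 0.1)
})

test_that("upper-quartile normalization uses the type-7 quartile of nonzero values", {
  skip_if_not(requireNamespace("stats", quietly = TRUE))
  v <- matrix(c(1, 2, 3, 4, 0, 2, 4, 6, 8, 0), 5,
              dimnames = list(rand_seq(5, 21), c("a", "b")))
  m <- expr_matrix(v, sample_hierarchy(list(T = c("a", "b"))))
  r <- normalize_upper_quartile(m)
  expect_equal(unname(r$factors), c(3.25, 6.5))
  # column b = 2x column a: equalized after scaling
  expect_equal(r$matrix$values[, "a"], r$matrix$values[, "b"])
})

test_that("TMM factors: identity on identical columns, depth-invariant on multiples", {
  m <- tiny_matrix(nseq = 200, seed = 8, factors = c(1, 1, 1, 1))
  r <- normalize_tmm(m)
  expect_equal(unname(r$factors), rep(1, 4), tolerance = 1e-9)
  m2 <- tiny_matrix(nseq = 200, seed = 8, factors = c(1, 2, 1, 1))
  r2 <- normalize_tmm(m2)
  # a pure depth difference is absorbed by the library size, not the factor,
  # and the normalized columns coincide
  expect_equal(r2$matrix$values[, "a1"], r2$matrix$values[, "a2"],
               tolerance = 1e-9)
  expect_equal(prod(r2$factors), 1, tolerance = 1e-12)
})

test_that("TMM trimming shrugs off a handful of extreme outliers", {
  set.seed(15)
  base <- rpois(1000, 50) + 1
  v <- cbind(r1 = base, r2 = rpois(1000, base))
  rownames(v) <- rand_seq(1000, 21)
  m <- expr_matrix(v, sample_hierarchy(list(T = c("r1", "r2"))))
  eff <- function(mm) {
    r <- normalize_tmm(mm, reference = "r1")
    s <- r$factors * colSums(mm$values)       # effective library sizes
    s[["r2"]] / s[["r1"]]
  }
  e0 <- eff(m)
  # add 5% extreme outlier sequences (massively up in r2, trace in r1)
  out <- cbind(r1 = rep(1, 50), r2 = rep(5000, 50))
  rownames(out) <- rand_seq(50, 22)
  e1 <- eff(expr_matrix(rbind(v, out), m$hierarchy))
  # the outliers blow up r2's raw column sum ~6-fold, yet they fall in
  # the trimmed M tail: relative scaling of the clean sequences moves by
  # under 1%
  expect_lt(abs(e1 / e0 - 1), 0.01)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  n <- 1500
  base <- round(rexp(n, 1 / 40)) + 1
  v <- sapply(c(1, 1.7, 0.6, 1.2), function(f) rpois(n, base * f))
  dimnames(v) <- list(rand_seq(n, 21), c("a1", "a2", "b1", "b2"))
  m <- expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"),
                                            B = c("b1", "b2"))))
  mine <- normalize_tmm(m)$factors
  ref <- edgeR::calcNormFactors(edgeR::DGEList(v), method = "TMM")
  expect_equal(unname(mine), unname(ref$samples$norm.factors),
               tolerance = 0.01)
})

test_that("median-of-ratios factors match the worked examples and DESeq2", {
  s <- rand_seq(3, 21)
  v <- matrix(c(1, 2, 4, 2, 4, 8), 3, dimnames = list(s, c("a", "b")))
  m <- expr_matrix(v, sample_hierarchy(list(T = c("a", "b"))))
  r <- normalize_deseq(m)
  expect_equal(unname(r$factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(r$matrix$values[, "a"], r$matrix$values[, "b"])
  # identical columns -> unit factors
  v2 <- matrix(c(1, 2, 4, 1, 2, 4), 3, dimnames = list(s, c("a", "b")))
  r2 <- normalize_deseq(expr_matrix(v2, m$hierarchy))
  expect_equal(unname(r2$factors), c(1, 1))
  skip_if_not_installed("DESeq2")
  m3 <- tiny_matrix(nseq = 300, seed = 13, factors = c(1, 1.5, 0.8, 1.1))
  expect_equal(unname(normalize_deseq(m3)$factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3$values)),
               tolerance = 1e-12)
})

test_that("adapted quantile normalization: rank means, tie averaging, zero pinning", {
  s <- rand_seq(3, 21)
  v <- matrix(c(2, 4, 0, 4, 8, 0), 3, dimnames = list(s, c("a", "b")))
  m <- expr_matrix(v[1:2, ], sample_hierarchy(list(T = c("a", "b"))))
  r <- normalize_quantile_adapted(m)
  expect_equal(unname(r$matrix$values[, "a"]), c(3, 6))
  expect_equal(unname(r$matrix$values[, "b"]), c(3, 6))
  # ties share the average of their reference values
  v2 <- matrix(c(5, 5, 10, 1, 2, 9), 3, dimnames = list(s, c("a", "b")))
  m2 <- expr_matrix(v2, sample_hierarchy(list(T = c("a", "b"))))
  r2 <- normalize_quantile_adapted(m2)   # reference = (3, 3.5, 9.5)
  expect_equal(unname(r2$matrix$values[, "a"]), c(3.25, 3.25, 9.5))
  # zeros stay exactly zero
  v3 <- matrix(c(0, 4, 3, 5), 2, dimnames = list(s[1:2], c("a", "b")))
  m3 <- expr_matrix(v3, sample_hierarchy(list(T = c("a", "b"))))
  expect_identical(normalize_quantile_adapted(m3)$matrix$values[1, "a"], 0)
})

test_that("adapted quantile equalizes nonzero multisets and is idempotent", {
  set.seed(19)
  v <- matrix(sample(1:1000, 120), 30, 4,
              dimnames = list(rand_seq(30, 21), c("a1", "a2", "b1", "b2")))
  m <- expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"),
                                            B = c("b1", "b2"))))
  r <- normalize_quantile_adapted(m)
  vals <- r$matrix$values
  for (j in 2:4) expect_equal(unname(sort(vals[, 1])), unname(sort(vals[, j])))
  r2 <- normalize_quantile_adapted(r$matrix)
  expect_equal(r2$matrix$values, vals)
})

test_that("subsampling hits the minimum library size exactly and reproducibly", {
  set.seed(23)
  v <- matrix(rpois(60, 8), 30, 2,
              dimnames = list(rand_seq(30, 21), c("a", "b")))
  v[, 2] <- v[, 2] * 3
  m <- expr_matrix(v, sample_hierarchy(list(T = c("a", "b"))))
  target <- min(colSums(v))
  r <- normalize_subsampling(m, seed = 5, n_boot = 20)
  expect_equal(unname(colSums(r$matrix$values)), c(target, target))
  expect_true(all(r$matrix$values <= v))          # without replacement
  expect_true(all(r$matrix$values[v == 0] == 0))
  r2 <- normalize_subsampling(m, seed = 5, n_boot = 20)
  expect_identical(r$matrix$values, r2$matrix$values)
  r3 <- normalize_subsampling(m, seed = 6, n_boot = 20)
  expect_equal(unname(colSums(r3$matrix$values)), c(target, target))
})

test_that("every method preserves zeros and non-negativity", {
  set.seed(31)
  v <- matrix(rpois(200, 10), 50, 4,
              dimnames = list(rand_seq(50, 21), c("a1", "a2", "b1", "b2")))
  v[sample(200, 40)] <- 0
  v[1, ] <- c(5, 6, 4, 7)    # guarantee an all-nonzero row for deseq
  m <- expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"),
                                            B = c("b1", "b2"))))
  for (meth in c("total_count", "upper_quartile", "tmm", "deseq",
                 "quantile_adapted", "subsampling")) {
    r <- if (meth == "subsampling") normalize_matrix(m, meth, seed = 2, n_boot = 10)
         else normalize_matrix(m, meth)
    expect_true(all(r$matrix$values >= 0), info = meth)
    expect_true(all(r$matrix$values[v == 0] == 0), info = meth)
  }
})

test_that("replicate-based evaluation ranks exact rescaling as perfectly centered", {
  set.seed(41)
  cn <- rpois(80, 60) + 1
  v <- cbind(r1 = cn, r2 = 2 * cn)
  rownames(v) <- rand_seq(80, 21)
  m <- expr_matrix(v, sample_hierarchy(list(T = c("r1", "r2"))))
  ev <- evaluate_normalizations(m, methods = c("raw", "total_count"))
  expect_equal(unname(ev$centering_scores["total_count"]), 0)
  expect_equal(unname(ev$centering_scores["raw"]), 1)   # log2(2)
  expect_equal(ev$ranking[1], "total_count")
})
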