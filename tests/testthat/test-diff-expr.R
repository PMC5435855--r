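ci <- function(lo, hi) list(lo = lo, hi = hi)

test_that("confidence intervals: min-max for 2 replicates, Chebyshev for more", {
  expect_equal(confidence_interval(c(3, 7))[c("lo", "hi")], list(lo = 3, hi = 7))
  ch <- confidence_interval(c(10, 12, 14), k = 2)
  expect_equal(ch$lo, 8)
  expect_equal(ch$hi, 16)
  deg <- confidence_interval(c(5, 5, 5))
  expect_equal(c(deg$lo, deg$hi), c(5, 5))
  expect_error(confidence_interval(3), "at least 2")
  # floored at zero: abundances cannot be negative
  expect_equal(confidence_interval(c(0, 1, 2), k = 3)$lo, 0)
  # wider k, wider interval; the interval always contains the mean
  k1 <- confidence_interval(c(4, 9, 11), k = 1)
  k3 <- confidence_interval(c(4, 9, 11), k = 3)
  expect_lt(k3$lo, k1$lo); expect_gt(k3$hi, k1$hi)
  expect_true(k1$lo <= 8 && 8 <= k1$hi)
})

test_that("interval comparison is an exhaustive, exclusive trichotomy", {
  expect_equal(compare_intervals(ci(0, 10), ci(5, 20)), "S")
  expect_equal(compare_intervals(ci(8, 16), ci(20, 30)), "U")
  expect_equal(compare_intervals(ci(20, 30), ci(8, 16)), "D")
  expect_equal(compare_intervals(ci(0, 10), ci(10, 20)), "S")  # touching
  set.seed(101)
  for (i in 1:10000) {
    a <- sort(runif(2, 0, 100)); b <- sort(runif(2, 0, 100))
    d1 <- compare_intervals(ci(a[1], a[2]), ci(b[1], b[2]))
    d2 <- compare_intervals(ci(b[1], b[2]), ci(a[1], a[2]))
    expect_true(d1 %in% c("U", "D", "S"))
    expect_equal(d2, switch(d1, U = "D", D = "U", S = "S"))
  }
})

test_that("LOFC matches its closed form and is antisymmetric", {
  expect_equal(lofc(126, 0, 42), 2)
  expect_equal(lofc(10, 10, 42), 0)
  set.seed(7)
  a <- runif(50, 0, 1000); b <- runif(50, 0, 1000)
  expect_equal(lofc(a, b, 42), -lofc(b, a, 42))
  expect_error(lofc(1, 1, 0), "offset")
})

test_that("descriptor calling demotes sub-threshold disjoint intervals to S", {
  # disjoint but LOFC = log2(45/44) < 1 -> S
  r <- call_descriptor(ci(0, 2), ci(3, 4), offset = 42)
  expect_equal(r$descriptor, "S")
  expect_equal(r$lofc, log2(45 / 44))
  # disjoint with LOFC = log2(168/44) > 1 -> U
  r2 <- call_descriptor(ci(0, 2), ci(126, 200), offset = 42)
  expect_equal(r2$descriptor, "U")
  expect_equal(r2$lofc, log2(168 / 44))
  # overlap -> S regardless of magnitudes
  r3 <- call_descriptor(ci(0, 1000), ci(500, 1e6), offset = 42)
  expect_equal(r3$descriptor, "S")
  # D mirror
  r4 <- call_descriptor(ci(126, 200), ci(0, 2), offset = 42)
  expect_equal(r4$descriptor, "D")
  expect_equal(r4$lofc, log2(44 / 168))
})

test_that("U/D calls always carry at least the threshold proximal ratio", {
  set.seed(12)
  off <- 42
  n_ud <- 0
  ok <- TRUE
  for (i in 1:500) {
    # disjoint by construction, then shifted by a common constant: the
    # shift shrinks the proximal ratio, so sub-ratio pairs must demote
    lo <- sort(runif(2, 0, 100)); gap <- runif(1, 0, 200)
    hi <- sort(runif(2, 0, 100)) + lo[2] + gap
    shift <- runif(1, 0, 500)
    r <- call_descriptor(ci(lo[1] + shift, lo[2] + shift),
                         ci(hi[1] + shift, hi[2] + shift), offset = off)
    if (r$descriptor == "U") {
      n_ud <- n_ud + 1
      ok <- ok && (hi[1] + shift + off) / (lo[2] + shift + off) >= 2
    }
  }
  expect_true(ok)
  expect_gt(n_ud, 0)     # the generator does produce genuine U calls
  # and a pair whose proximal ratio is diluted below 2 by a large shift is S
  expect_equal(call_descriptor(ci(100, 110), ci(150, 160), offset = 42,
                               threshold = 1)$descriptor, "S")
})

test_that("call_de builds patterns over consecutive comparisons", {
  set.seed(55)
  seqs <- rand_seq(6, 21)
  flat <- rpois(6, 200) + 50
  v <- cbind(t1a = flat, t1b = flat, t2a = flat, t2b = flat,
             t3a = flat, t3b = flat)
  # sequence 1: x8 spike between T1 and T2, flat after (pattern "US")
  v[1, ] <- c(900, 1100, 8 * 1000 * 0.9, 8 * 1000 * 1.1, 7500, 8500)
  rownames(v) <- seqs
  h <- sample_hierarchy(list(T1 = c("t1a", "t1b"), T2 = c("t2a", "t2b"),
                             T3 = c("t3a", "t3b")))
  m <- expr_matrix(v, h)
  de <- call_de(m, offset = 42)
  expect_equal(nchar(de$pattern), rep(2L, 6))
  expect_equal(de$pattern[de$sequence == seqs[1]], "US")
  expect_true(all(de$pattern[de$sequence != seqs[1]] == "SS"))
  expect_equal(de$de_flag, de$sequence == seqs[1])
  # the spiked sequence ranks first; all-S sequences carry -Inf rank keys
  expect_equal(de$sequence[1], seqs[1])
  expect_true(all(is.infinite(de$rank_lofc[-1])))
})

test_that("vs-reference scheme compares every treatment to the named one", {
  m <- tiny_matrix(seed = 3)
  h3 <- sample_hierarchy(list(A = c("a1", "a2"), B = c("b1", "b2")))
  de <- call_de(m, offset = 10, scheme = "vs_reference", reference = "A")
  expect_equal(attr(de, "comparisons")$reference, "A")
  expect_error(call_de(m, offset = 10, scheme = "vs_reference",
                       reference = "Z"), "unknown reference")
})

test_that("swapping treatments maps U to D and negates the LOFC", {
  set.seed(66)
  seqs <- rand_seq(20, 21)
  v <- cbind(a1 = rpois(20, 500), a2 = rpois(20, 500),
             b1 = rpois(20, 2500), b2 = rpois(20, 2500))
  rownames(v) <- seqs
  m1 <- expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"),
                                             B = c("b1", "b2"))))
  m2 <- expr_matrix(v, sample_hierarchy(list(B = c("b1", "b2"),
                                             A = c("a1", "a2"))))
  d1 <- call_de(m1, offset = 42); d2 <- call_de(m2, offset = 42)
  d2 <- d2[match(d1$sequence, d2$sequence), ]
  swap <- c(U = "D", D = "U", S = "S")
  expect_equal(unname(swap[d1$desc_A_vs_B]), d2$desc_B_vs_A)
  ud <- d1$desc_A_vs_B != "S"
  expect_equal(d1$lofc_A_vs_B[ud], -d2$lofc_B_vs_A[ud])
})

test_that("pattern clustering partitions sequences and filters the headline", {
  set.seed(77)
  seqs <- rand_seq(30, 21)
  calls <- data.frame(sequence = seqs,
                      pattern = c(rep("US", 20), rep("DU", 3), rep("SS", 7)),
                      stringsAsFactors = FALSE)
  cl <- cluster_patterns(calls, min_size = 15)
  expect_setequal(unlist(cl$full), seqs)
  expect_equal(sum(lengths(cl$full)), 30L)
  expect_equal(names(cl$headline), "US")     # DU too small, SS dropped
  cl2 <- cluster_patterns(calls, min_size = 2, drop_all_s = FALSE)
  expect_setequal(names(cl2$headline), c("US", "DU", "SS"))
  all_s <- data.frame(sequence = seqs, pattern = "SS")
  expect_equal(length(cluster_patterns(all_s, 15)$headline), 0L)
})

test_that("null experiments produce almost no U/D calls", {
  # replicates drawn from the same distribution, 20 seeded repetitions
  rate <- vapply(1:20, function(s) {
    set.seed(s + 400)
    n <- 300
    base <- round(rexp(n, 1 / 60)) + 1
    noise <- function() round(base * exp(rnorm(n, 0, 0.1)))
    v <- cbind(a1 = noise(), a2 = noise(), b1 = noise(), b2 = noise())
    rownames(v) <- rand_seq(n, 21)
    m <- expr_matrix(v, sample_hierarchy(list(A = c("a1", "a2"),
                                              B = c("b1", "b2"))))
    de <- call_de(m, offset = 50)
    mean(de$de_flag)
  }, numeric(1))
  expect_lte(mean(rate), 0.01)
})
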