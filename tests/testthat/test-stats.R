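test_that("column-minimum imputation fills gaps with each column's minimum", {
  expect_equal(impute_column_min(cbind(c(4, NA, 8)))[, 1], c(4, 4, 8))

  m <- matrix(1:9, 3)
  expect_equal(impute_column_min(m), m)

  m3 <- withr::with_seed(1, matrix(runif(9, 1, 10), 3))
  m3[cbind(1:3, 1:3)] <- NA
  imp <- impute_column_min(m3)
  for (j in 1:3) {
    # brute-force per-column scan as the oracle
    expect_equal(imp[j, j], min(m3[, j], na.rm = TRUE))
    expect_equal(imp[-j, j], m3[-j, j])
  }

  bad <- cbind(a = c(1, 2), b = c(NA, NA))
  expect_error(impute_column_min(bad), "b")
})

test_that("imputation never alters present values nor lowers a column minimum", {
  for (seed in 1:10) {
    m <- withr::with_seed(seed, matrix(runif(60, 1, 100), 20, 3))
    m[withr::with_seed(seed + 100, sample(60, 10))] <- NA
    imp <- impute_column_min(m)
    expect_equal(imp[!is.na(m)], m[!is.na(m)])
    expect_true(all(apply(imp, 2, min) >= apply(m, 2, min, na.rm = TRUE)))
  }
})

test_that("log2 transform is exact and rejects non-positive cells", {
  expect_equal(log2_transform(8), 3)
  expect_equal(log2_transform(1), 0)
  expect_equal(log2_transform(10), 3.32192809488736, tolerance = 1e-14)
  expect_error(log2_transform(matrix(c(1, 0, 2, 3), 2)), "row 2, column 1")
})

test_that("Student t matches the textbook pooled formula and t.test", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  res <- two_sample_t(a, b)
  # independent evaluation from the pooled-variance formula
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_ref), 4), tolerance = 1e-12)

  w <- two_sample_t(c(1, 5, 9, 2), c(3, 3.5, 4), variant = "welch")
  ref <- t.test(c(1, 5, 9, 2), c(3, 3.5, 4))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$p, unname(ref$p.value), tolerance = 1e-12)
})

test_that("t test conventions: identical groups, constants, group size", {
  eq <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_equal(two_sample_t(c(2, 2), c(2, 2)), list(t = 0, p = 1))
  const <- two_sample_t(c(3, 3), c(1, 1))
  expect_equal(const$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("t test is antisymmetric in group order", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, list(a = rnorm(4), b = rnorm(5)))
    ab <- two_sample_t(x$a, x$b)
    ba <- two_sample_t(x$b, x$a)
    expect_equal(ab$t, -ba$t)
    expect_equal(ab$p, ba$p)
  }
})

test_that("Student p agrees with the exact permutation distribution", {
  x <- withr::with_seed(42, rnorm(8))
  a <- x[1:4]
  b <- x[5:8]
  obs <- abs(mean(a) - mean(b))
  # enumerate all C(8,4) relabelings: an independent oracle
  splits <- utils::combn(8, 4)
  perm_stats <- apply(splits, 2, function(i) abs(mean(x[i]) - mean(x[-i])))
  p_perm <- mean(perm_stats >= obs - 1e-12)
  p_t <- two_sample_t(a, b)$p
  expect_lt(abs(p_t - p_perm), 0.12)
})

test_that("row-wise t helpers agree with the scalar implementation", {
  set.seed(5)
  A <- matrix(rnorm(30), 10)
  B <- matrix(rnorm(30, 0.5), 10)
  rr <- parpiomics:::row_t_student(A, B)
  for (i in c(1, 4, 10)) {
    ref <- two_sample_t(A[i, ], B[i, ])
    expect_equal(rr$t[i], ref$t, tolerance = 1e-12)
    expect_equal(rr$p[i], ref$p, tolerance = 1e-12)
  }
  r1 <- parpiomics:::row_t_onesample(A)
  ref1 <- t.test(A[3, ])
  expect_equal(r1$t[3], unname(ref1$statistic), tolerance = 1e-12)
  expect_equal(r1$p[3], unname(ref1$p.value), tolerance = 1e-12)
})

test_that("BH adjustment follows the hand step-up and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  # step-up by hand: sorted p (0.01, 0.02, 0.03); q_(i) = min_{j>=i} p_(j)*3/j
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(30))
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    perm <- withr::with_seed(seed + 50, sample(30))
    expect_equal(bh_adjust(p[perm])[order(perm)], q)
  }
})

test_that("adaptive threshold averages per-replicate spreads and scales them", {
  # two features, two replicates with classical SDs exactly 0.2 and 0.4
  a <- 0.2 / sqrt(2)
  b <- 0.4 / sqrt(2)
  lfc <- cbind(c(-a, a), c(-b, b))
  thr <- adaptive_sd_threshold(lfc, estimator = "sd")
  expect_equal(thr$average_sd, 0.3)
  expect_equal(thr$threshold, 0.6)

  expect_error(adaptive_sd_threshold(cbind(c(1, 2))), "2 replicate")
})

test_that("adaptive threshold converges to 2 sigma on null data", {
  lfc <- withr::with_seed(7, matrix(rnorm(4000 * 3, 0, 0.3), 4000, 3))
  expect_equal(adaptive_sd_threshold(lfc)$threshold, 0.6, tolerance = 0.05)
  expect_equal(adaptive_sd_threshold(lfc, estimator = "sd")$threshold, 0.6,
               tolerance = 0.05)
})
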