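# Core equality LRT: MLE summaries, the Wn statistic, marginal and
# conditional forms, and their invariances.

test_that("MLE summaries use likelihood divisors and the grand mean", {
  d <- two_sample_data(matrix(c(0, 2), 2, 1), matrix(c(1, 3), 2, 1),
                       labels = "x")
  m <- mle_summary(d)
  expect_equal(unname(m$cov_1[1, 1]), 1)    # divisor 2, not 1
  expect_equal(unname(m$cov_2[1, 1]), 1)
  expect_equal(unname(m$mean_pooled), 1.5)
  # mean of squares minus squared mean over all four points
  expect_equal(unname(m$cov_pooled[1, 1]), (0 + 4 + 1 + 9) / 4 - 1.5^2)
})

test_that("identical samples give identical group and pooled summaries", {
  set.seed(42)
  x <- matrix(rnorm(10), 5, 2)
  m <- mle_summary(two_sample_data(x, x))
  expect_equal(m$mean_1, m$mean_2)
  expect_equal(m$mean_1, m$mean_pooled)
  expect_equal(m$cov_1, m$cov_pooled)
})

test_that("existence preconditions are enforced at the boundary", {
  set.seed(1)
  # nj < p + 1: even the covariance MLE is singular
  d0 <- two_sample_data(matrix(rnorm(9), 3, 3), matrix(rnorm(30), 10, 3))
  expect_error(mle_summary(d0), "p \\+ 1")
  # nj = p + 1: MLE exists but the LRT does not
  d <- two_sample_data(matrix(rnorm(12), 4, 3), matrix(rnorm(30), 10, 3))
  expect_s3_class(mle_summary(d), "mle_summary")
  expect_error(wn_statistic(d), "n_j > p \\+ 1")
  expect_error(two_sample_data(matrix(c(1, NA, 3, 4), 2), matrix(1:4, 2)),
               "missing")
  # numerically singular: duplicated column
  x <- matrix(rnorm(40), 20, 2)
  d2 <- two_sample_data(cbind(x, x[, 1]), matrix(rnorm(60), 20, 3))
  expect_error(wn_statistic(d2), "singular")
})

test_that("Wn is zero when the second sample copies the first", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  r <- wn_statistic(two_sample_data(x, x))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  expect_equal(r$df, equality_df(3))
})

test_that("Wn matches a brute-force likelihood maximization at p = 1", {
  set.seed(3)
  x1 <- rnorm(12, 1, 2); x2 <- rnorm(15, 0.5, 1.5)
  r <- wn_statistic(two_sample_data(matrix(x1), matrix(x2)))
  expect_equal(r$statistic, brute_force_wn_1d(x1, x2), tolerance = 1e-6)
})

test_that("Wn is affine invariant and invariant to row/column permutations", {
  set.seed(4)
  d <- null_pair(3, 20)
  w0 <- wn_statistic(d)$statistic
  for (rep in 1:3) {
    a <- matrix(rnorm(9), 3); while (abs(det(a)) < 0.1) a <- matrix(rnorm(9), 3)
    b <- rnorm(3)
    dt <- two_sample_data(sweep(d$x1 %*% a, 2, b, `+`),
                          sweep(d$x2 %*% a, 2, b, `+`), labels = d$labels)
    expect_equal(wn_statistic(dt)$statistic, w0, tolerance = 1e-8)
  }
  # row permutation (summation order may differ in the last bits)
  dp <- two_sample_data(d$x1[sample(20), ], d$x2[sample(20), ],
                        labels = d$labels)
  expect_equal(wn_statistic(dp)$statistic, w0, tolerance = 1e-10)
  # consistent column permutation
  perm <- c(3, 1, 2)
  dc <- two_sample_data(d$x1[, perm], d$x2[, perm], labels = d$labels[perm])
  expect_equal(wn_statistic(dc)$statistic, w0, tolerance = 1e-10)
})

test_that("marginal Wn reduces to the column-subset statistic", {
  set.seed(5)
  d <- null_pair(4, 25)
  full <- marginal_wn(d, d$labels)
  expect_equal(full$statistic, wn_statistic(d)$statistic)
  one <- marginal_wn(d, "2")
  expect_equal(one$df, 2L)  # p = 1 gives f = 2
  expect_equal(one$statistic,
               wn_statistic(subset_data(d, "2"))$statistic)
  expect_error(marginal_wn(d, "nope"), "unknown variable")
  expect_error(marginal_wn(d, character()), "non-empty")
})

test_that("conditional Wn is the telescoping difference with df fA - fB", {
  set.seed(6)
  d <- null_pair(3, 30)
  ab <- conditional_wn(d, c("1", "2"), "2")
  expect_equal(ab$statistic,
               marginal_wn(d, c("1", "2"))$statistic -
                 marginal_wn(d, "2")$statistic)
  expect_equal(ab$df, equality_df(2) - equality_df(1))
  expect_identical(ab$subset, "1")
  expect_identical(ab$conditioning, "2")
  # empty conditioning set reduces to the marginal test
  expect_equal(conditional_wn(d, c("1", "3"))$statistic,
               marginal_wn(d, c("1", "3"))$statistic)
  expect_error(conditional_wn(d, c("1", "2"), "3"), "strictly contained")
  expect_error(conditional_wn(d, c("1", "2"), c("1", "2")),
               "strictly contained")
})

test_that("null mean of the conditional statistic matches the exact moment
           difference", {
  set.seed(7)
  reps <- 600
  w <- numeric(reps)
  for (r in seq_len(reps))
    w[r] <- conditional_wn(null_pair(3, 50), c("1", "2", "3"), "1")$statistic
  expected <- wn_null_moments(3, 50, 50)$mean - wn_null_moments(1, 50, 50)$mean
  expect_lt(abs(mean(w) - expected), 3 * sd(w) / sqrt(reps))
  # and the asymptotic reference (the df) is close by
  expect_lt(abs(expected - 7) / 7, 0.1)
})

test_that("statistics are nonnegative across random null draws", {
  set.seed(8)
  for (r in 1:20) {
    d <- null_pair(sample(1:5, 1), 30)
    expect_gte(wn_statistic(d)$statistic, 0)
    if (length(d$labels) >= 2)
      expect_gte(conditional_wn(d, d$labels, d$labels[1])$statistic, 0)
  }
})

test_that("chi-square p-values follow the upper tail", {
  expect_equal(chi2_pvalue(0, 5), 1)
  expect_equal(chi2_pvalue(5.991, 2), 0.05, tolerance = 1e-3)
  expect_lt(abs(chi2_pvalue(1000, 1000) - 0.5), 0.01)  # median near df
  expect_error(chi2_pvalue(-1, 2), "nonnegative")
})
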