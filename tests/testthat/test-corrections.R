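# Correction factors: degrees of freedom, rho, mu_wn/delta, CLT z-score,
# and the exact null moments that anchor them.

test_that("equality test degrees of freedom are p(p+3)/2", {
  expect_identical(equality_df(c(2, 30, 40)), c(5L, 495L, 860L))
  expect_identical(equality_df(1), 2L)
  expect_error(equality_df(0), "positive")
})

test_that("rho matches an exact hand transcription and its limits", {
  # p = 2, n1 = n2 = 50: 1 - 37 * 3 / (6 * 5 * 100) = 1 - 111/3000
  expect_equal(rho_factor(2, 50, 50), 1 - 111 / 3000)
  # correction vanishes as n grows
  expect_equal(rho_factor(2, 1e8, 1e8), 1, tolerance = 1e-6)
  # strictly decreasing in p at fixed sizes
  vals <- vapply(1:40, rho_factor, numeric(1), n1 = 50, n2 = 50)
  expect_true(all(diff(vals) < 0))
})

test_that("exact null moments agree with Monte Carlo", {
  set.seed(21)
  reps <- 3000
  for (cfg in list(c(3, 20, 30), c(8, 12, 15))) {
    p <- cfg[1]; n1 <- cfg[2]; n2 <- cfg[3]
    w <- numeric(reps)
    for (r in seq_len(reps))
      w[r] <- wn_statistic(two_sample_data(
        matrix(rnorm(n1 * p), n1), matrix(rnorm(n2 * p), n2)))$statistic
    ex <- wn_null_moments(p, n1, n2)
    expect_lt(abs(mean(w) - ex$mean), 3 * sd(w) / sqrt(reps))
    expect_lt(abs(var(w) - ex$var) / ex$var, 0.1)
  }
})

test_that("mu_wn tracks the exact null mean and approaches f from above", {
  for (cfg in list(c(2, 50, 50), c(10, 50, 50), c(40, 50, 50),
                   c(8, 10, 10), c(80, 100, 100))) {
    p <- cfg[1]
    expect_equal(mu_wn(p, cfg[2], cfg[3]),
                 wn_null_moments(p, cfg[2], cfg[3])$mean,
                 tolerance = 0.04)
  }
  # monotone approach of mu_wn/f to 1 with growing n at fixed p
  ratios <- vapply(10^(2:5), function(n) mu_wn(3, n, n) / equality_df(3),
                   numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(abs(ratios[4] - 1), 1e-3)
  # symmetry in the two group sizes
  expect_equal(mu_wn(4, 30, 90), mu_wn(4, 90, 30))
  expect_error(mu_wn(10, 11, 50), "p \\+ 1")
})

test_that("the alternative reading of the group factor is rejected by the
           exact-mean oracle", {
  for (cfg in list(c(5, 50, 50), c(30, 50, 50), c(8, 10, 10))) {
    ex <- wn_null_moments(cfg[1], cfg[2], cfg[3])$mean
    err_default <- abs(mu_wn(cfg[1], cfg[2], cfg[3]) - ex)
    err_alt <- abs(mu_wn(cfg[1], cfg[2], cfg[3],
                         last_factor = "njprime") - ex)
    expect_lt(err_default, err_alt)
    expect_gt(err_alt / ex, 0.1)   # the alternative is not a close call
  }
})

test_that("delta factor identities and comparison with rho", {
  spec <- delta_factor(40, 50, 50)
  expect_equal(spec$factor * mu_wn(40, 50, 50), equality_df(40),
               tolerance = 1e-12)
  expect_gt(spec$factor, 0)
  expect_lt(spec$factor, 1)
  # delta corrects more aggressively than rho near p ~ n
  expect_lt(spec$factor, rho_factor(40, 50, 50))
  # consistency with the uncorrected test as n grows
  expect_equal(delta_factor(2, 1e6, 1e6)$factor, 1, tolerance = 1e-4)
})

test_that("delta and rho agree in the classical small-p regime", {
  for (p in c(1, 2, 4)) {
    for (n in c(120, 300, 500)) {
      if (p / (2 * n) < 0.05)
        expect_equal(delta_factor(p, n, n)$factor, rho_factor(p, n, n),
                     tolerance = 0.01)
    }
  }
})

test_that("mu_wn exceeds f over the admissible grid (hence delta < 1)", {
  set.seed(22)
  for (r in 1:60) {
    p <- sample(1:40, 1)
    n1 <- sample((p + 2):500, 1)
    n2 <- sample((p + 2):500, 1)
    expect_gt(mu_wn(p, n1, n2), equality_df(p))
  }
})

test_that("corrected_test rescales the statistic and recomputes the p-value", {
  set.seed(23)
  d <- null_pair(3, 30)
  base <- wn_statistic(d)
  id <- corrected_test(base, correction_spec("none", 3, 30, 30))
  expect_equal(id$statistic, base$statistic)
  delta <- corrected_test(base, delta_factor(3, 30, 30))
  expect_equal(delta$statistic, base$statistic * delta$factor)
  expect_equal(delta$p.value, chi2_pvalue(delta$statistic, 9))
  expect_error(corrected_test(delta, delta_factor(3, 30, 30)),
               "already corrected")
  expect_error(corrected_test(base, delta_factor(4, 30, 30)),
               "degrees of freedom")
  # zero stays zero with p-value one
  x <- matrix(rnorm(90), 30, 3)
  z <- corrected_test(wn_statistic(two_sample_data(x, x)),
                      delta_factor(3, 30, 30))
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
})

test_that("CLT z-score is centered and scaled under the null, but skewed at
           small p", {
  set.seed(24)
  reps <- 1200
  z <- numeric(reps)
  for (r in seq_len(reps)) {
    w <- wn_statistic(null_pair(10, 50))$statistic
    z[r] <- clt_zscore(-w / 2, 10, 50, 50)$statistic
  }
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
  # at p = 2 the normal approximation fails visibly: skewness beyond 3 SE
  z2 <- numeric(reps)
  for (r in seq_len(reps)) {
    w <- wn_statistic(null_pair(2, 50))$statistic
    z2[r] <- clt_zscore(-w / 2, 2, 50, 50)$statistic
  }
  skew <- mean((z2 - mean(z2))^3) / sd(z2)^3
  expect_gt(abs(skew), 3 * sqrt(6 / reps))
  # rejection direction: large Wn means small z and small p-value
  big <- clt_zscore(-500, 10, 50, 50)
  expect_lt(big$statistic, 0)
  expect_lt(big$p.value, 1e-6)
})

test_that("implemented dispersion term matches the empirical spread of
           log Lambda", {
  set.seed(25)
  reps <- 1500
  ll <- numeric(reps)
  for (r in seq_len(reps))
    ll[r] <- -wn_statistic(null_pair(30, 100))$statistic / 2
  expect_lt(abs(sqrt(wn_null_moments(30, 100, 100)$var) / 2 - sd(ll)) /
              sd(ll), 0.1)
})
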