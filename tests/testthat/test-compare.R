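test_that("reduced chi-square handles identity, unit residuals and models", {
  q <- seq(0.01, 0.2, by = 0.01)
  a <- sas_profile(q, rep(5, 20), rep(1, 20))
  expect_equal(chi2_compare(a, a)$chi2_reduced, 0)
  # alternating +-1 pooled-sigma residuals give exactly 1
  b <- sas_profile(q, 5 + sqrt(2) * rep(c(1, -1), 10), rep(1, 20))
  expect_equal(chi2_compare(a, b)$chi2_reduced, 1)
  # model curves carry no error
  expect_equal(chi2_compare(a, rep(4, 20), model = TRUE)$chi2_reduced, 1)
  expect_equal(chi2_compare(a, rep(4, 20), n_fitted = 10, model = TRUE)$dof, 10)
  expect_error(chi2_compare(a, sas_profile(q + 0.001, rep(5, 20), rep(1, 20))),
               "rebin")
  # scale consistency: multiplying I and sigma by c leaves chi2 unchanged
  a2 <- sas_profile(q, 3 * a$I, 3 * a$sigma)
  b2 <- sas_profile(q, 3 * b$I, 3 * b$sigma)
  expect_equal(chi2_compare(a2, b2)$chi2_reduced, 1)
})

test_that("paired noise realizations give chi-square near one", {
  q <- seq(0.002, 0.4, by = 0.002)
  sp <- sphere_profile(20, 1, q)
  ch <- vapply(1:20, function(s) {
    x <- simulate_instrument(sp, noise_k = 0.01, floor = 0.01, seed = 3000 + 2 * s)
    y <- simulate_instrument(sp, noise_k = 0.01, floor = 0.01, seed = 3001 + 2 * s)
    chi2_compare(x, y)$chi2_reduced
  }, numeric(1))
  n <- length(q)
  expect_lt(abs(mean(ch) - 1), 3 * sqrt(2 / n) / sqrt(20))
  expect_true(all(abs(ch - 1) < 5 * sqrt(2 / n)))
})

test_that("longest-run statistic and exact tail probability match enumeration", {
  # sign handling: zeros inherit the previous sign, leading zeros positive
  expect_equal(longest_sign_run(c(1, 1, -1)), 2L)
  expect_equal(longest_sign_run(c(0, 0, -1)), 2L)
  expect_equal(longest_sign_run(c(1, 0, 0, -1)), 3L)
  # brute-force enumeration oracle for all n <= 12, all C
  brute <- function(n, C) {
    cnt <- 0L
    for (x in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(x))[1:n]
      if (max(rle(bits)$lengths) >= C) cnt <- cnt + 1L
    }
    cnt / 2^n
  }
  for (n in c(5L, 8L, 12L)) {
    for (C in 1:n) expect_equal(cormap_pvalue(n, C), brute(n, C),
                                tolerance = 1e-12)
  }
  # closed-form anchor points
  expect_equal(cormap_pvalue(5, 5), 2 / 32)
  expect_equal(cormap_pvalue(10, 1), 1)
})

test_that("the correlation-map test is symmetric and Bonferroni-adjusted", {
  q <- seq(0.01, 0.2, by = 0.002)
  n <- length(q)
  set.seed(9)
  a <- sas_profile(q, 5 + rnorm(n), rep(1, n))
  b <- sas_profile(q, 5 + rnorm(n), rep(1, n))
  r1 <- cormap_test(a, b)
  r2 <- cormap_test(b, a)
  expect_equal(r1$cormap_C, r2$cormap_C)
  expect_equal(r1$cormap_P, r2$cormap_P)
  r5 <- cormap_test(a, b, n_comparisons = 5)
  expect_equal(r5$cormap_P_adjusted, min(1, 5 * r1$cormap_P))
  expect_gte(r5$cormap_P_adjusted, r5$cormap_P)
  # all-positive differences of length 5: the anchor case
  a5 <- sas_profile(q[1:5], rep(6, 5), rep(1, 5))
  b5 <- sas_profile(q[1:5], rep(5, 5), rep(1, 5))
  r <- cormap_test(a5, b5)
  expect_equal(r$cormap_C, 5L)
  expect_equal(r$cormap_P, 0.0625)
  expect_error(cormap_test(sas_profile(q[1:4], 1:4, rep(1, 4)),
                           sas_profile(q[1:4], 2:5, rep(1, 4))), "at least 5")
})

test_that("error-weighted residuals flag systematic deviations", {
  q <- seq(0.01, 0.5, by = 0.0002)
  n <- length(q)
  a <- sas_profile(q, rep(5, n), rep(1, n))
  expect_equal(residual_plot_data(a, a)$residuals, rep(0, n))
  set.seed(17)
  b <- sas_profile(q, 5 + rnorm(n) * sqrt(2), rep(1, n))
  rp <- residual_plot_data(a, b)
  expect_lt(rp$frac_outside_3sigma, 0.01)   # ~0.3% expected for Gaussian
  expect_false(rp$systematic)
  # a +2 pooled-sigma offset everywhere is declared systematic
  c2 <- sas_profile(q, rep(5 + 2 * sqrt(2), n), rep(1, n))
  rp2 <- residual_plot_data(a, c2)
  expect_true(all(abs(rp2$residuals) >= 2 - 1e-12))
  expect_true(rp2$systematic)
})

test_that("full comparison object carries all three diagnostics", {
  q <- seq(0.01, 0.2, by = 0.002)
  set.seed(4)
  a <- sas_profile(q, 5 + rnorm(length(q)), rep(1, length(q)))
  b <- sas_profile(q, 5 + rnorm(length(q)), rep(1, length(q)))
  cmp <- compare_profiles(a, b, n_comparisons = 2)
  expect_s3_class(cmp, "sas_comparison")
  expect_true(all(c("chi2_reduced", "cormap_C", "cormap_P",
                    "cormap_P_adjusted", "frac_outside_3sigma") %in% names(cmp)))
  expect_output(print(cmp), "CorMAP")
})
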