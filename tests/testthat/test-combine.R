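test_that("fit_scales recovers affine maps between datasets exactly", {
  q <- seq(0.0025, 0.3, by = 0.005)
  base <- sphere_profile(20, 1, q)
  p1 <- sas_profile(q, base$I, rep(0.01, length(q)))
  # identical profiles: unit scales, zero offsets, zero objective
  sc0 <- fit_scales(list(p1, p1), reference = 1)
  expect_equal(sc0$a, c(1, 1), tolerance = 1e-8)
  expect_equal(sc0$b, c(0, 0), tolerance = 1e-10)
  expect_lt(sc0$objective_f, 1e-15)
  # dataset2 = 2 * dataset1 + 5 (intensity units scaled down): invert analytically
  p2 <- sas_profile(q, 2 * base$I + 0.005, rep(0.01, length(q)))
  sc <- fit_scales(list(p1, p2), reference = 1)
  expect_equal(sc$a[2], 0.5, tolerance = 1e-6)
  expect_equal(sc$b[2], -0.0025, tolerance = 1e-6)
  expect_true(sc$converged)
  # gauge invariants
  expect_equal(sc$a[sc$reference], 1)
  expect_equal(sc$b[sc$reference], 0)
  expect_true(all(sc$a > 0))
})

test_that("fit_scales recovers planted parameters within uncertainty on noisy replicas", {
  q <- seq(0.0025, 0.3, by = 0.0025)
  ideal <- sphere_profile(20, 1, q)
  planted_a <- c(1, 3, 0.5)
  planted_b <- c(0, 0.02, -0.01)
  profs <- lapply(1:3, function(j)
    simulate_instrument(ideal, a = planted_a[j], b = planted_b[j],
                        noise_k = 0.01, seed = 60 + j))
  sc <- fit_scales(profs, reference = 1)
  # gauge: a_hat[j] maps dataset j onto dataset 1's scale
  a_exp <- planted_a[1] / planted_a
  b_exp <- planted_b[1] - planted_a[1] * planted_b / planted_a
  for (j in 2:3) {
    expect_lt(abs(sc$a[j] - a_exp[j]), 3 * sc$se_a[j])
    expect_lt(abs(sc$b[j] - b_exp[j]), 3 * sc$se_b[j])
  }
})

test_that("the error filter keeps the propagated-error-minimising prefix", {
  expect_identical(error_filter(1), TRUE)
  expect_identical(error_filter(c(1, 1, 10)), c(TRUE, TRUE, FALSE))
  expect_true(all(error_filter(rep(1, 4))))
  # the filtered propagated error never exceeds the all-points average error
  set.seed(21)
  for (k in 1:200) {
    s <- runif(sample(2:12, 1), 0.1, 5)
    inc <- error_filter(s)
    g_inc <- sqrt(sum(s[inc]^2)) / sum(inc)
    g_all <- sqrt(sum(s^2)) / length(s)
    expect_lte(g_inc, g_all + 1e-12)
    expect_true(inc[which.min(s)])   # the best point is always kept
  }
})

test_that("the modified Z-score flags gross outliers and respects degeneracy", {
  # all equal: no removals
  r0 <- outlier_filter(rep(5, 6))
  expect_true(r0$degenerate)
  expect_false(any(r0$removed))
  # hand-computed example: only the gross value is removed
  r <- outlier_filter(c(10.0, 10.2, 9.9, 10.1, 20.0))
  expect_equal(r$med, 10.1)
  expect_equal(r$mad, 0.1)
  expect_equal(r$z[5], 0.6745 * 9.9 / 0.1, tolerance = 1e-12)
  expect_identical(r$removed, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(r$z[3], 0.6745 * 0.2 / 0.1, tolerance = 1e-12)  # 1.35: kept
  # MAD = 0: degenerate, nothing removed
  r2 <- outlier_filter(c(5, 5, 5, 9))
  expect_true(r2$degenerate)
  expect_false(any(r2$removed))
  # fewer than 3 values: no removal attempted
  expect_false(any(outlier_filter(c(1, 100))$removed))
})

test_that("noise-free affine campaigns are recovered exactly up to gauge", {
  set.seed(31)
  a <- c(1, exp(runif(4, -1, 1)))
  b <- c(0, runif(4, -0.01, 0.01))
  grid <- qgrid(c(0, 0.4, 0.005))
  profs <- affine_campaign(a, b, R = 20, grid = grid)
  cons <- sas_combine(profs, grid, filter = "both", reference = 1)
  expect_equal(cons$scaling$a, 1 / a, tolerance = 1e-6)
  expect_equal(cons$scaling$b, -b / a, tolerance = 1e-8)
  expect_equal(sum(cons$exclusion_reason == "outlier"), 0L)
  ideal <- sphere_profile(20, 1, grid$centers)
  expect_equal(cons$consensus$I, ideal$I, tolerance = 1e-7)
})

test_that("a planted gross spike is flagged and the consensus averages the rest", {
  q <- seq(0.0025, 0.4, by = 0.0025)
  ideal <- sphere_profile(20, 1, q)
  profs <- lapply(1:6, function(j)
    simulate_instrument(ideal, a = j / 2, b = 0.001 * (j - 3), noise_k = 0.01,
                        outlier_idx = if (j == 4) 60L else integer(0),
                        outlier_mult = 10, seed = 70 + j))
  grid <- qgrid(c(0, 0.4, 0.005))
  cons <- sas_combine(profs, grid, filter = "outlier")
  bin <- findInterval(q[60], grid$edges)
  expect_identical(cons$exclusion_reason[4, bin], "outlier")
  expect_equal(sum(cons$inclusion[, bin]), 5L)
  expect_true(bin %in% match(cons$consensus$q, cons$q))
})

test_that("gauge invariance: a common prefactor rescales the consensus linearly", {
  q <- seq(0.0025, 0.4, by = 0.005)
  ideal <- sphere_profile(20, 1, q)
  profs <- lapply(1:4, function(j)
    simulate_instrument(ideal, a = j, b = 0, noise_k = 0.01, seed = 80 + j))
  grid <- qgrid(c(0, 0.4, 0.005))
  c1 <- sas_combine(profs, grid, filter = "none", reference = 1)
  profs10 <- lapply(profs, function(p) sas_profile(p$q, 10 * p$I, 10 * p$sigma))
  c2 <- sas_combine(profs10, grid, filter = "none", reference = 1)
  expect_equal(c2$consensus$I, 10 * c1$consensus$I, tolerance = 1e-8)
  expect_equal(c2$consensus$sigma, 10 * c1$consensus$sigma, tolerance = 1e-8)
})

test_that("filter modes agree on clean data and the objective settles", {
  camp <- simulate_campaign(campaign_config(), master_seed = 12)
  grid <- qgrid(c(0, 0.5, 0.005))
  both <- sas_combine(camp$profiles, grid, filter = "both")
  none <- sas_combine(camp$profiles, grid, filter = "none")
  i <- match(none$consensus$q, both$consensus$q)
  ok <- !is.na(i)
  z <- abs(both$consensus$I[i[ok]] - none$consensus$I[ok]) / none$consensus$sigma[ok]
  expect_lt(median(z), 1)        # filters leave the curve essentially unchanged
  expect_lt(max(z), 5)
  # final pairwise objective never above the unfiltered starting point
  expect_lte(both$f_history[length(both$f_history)], both$f_history[1] + 1e-9)
  # consensus error model: sigma = sqrt(sum a^2 s^2)/M over included
  k <- which(ok)[1]; ib <- i[k]
  q_i <- match(both$consensus$q[ib], both$q)
  inc <- both$inclusion[, q_i]
  expect_equal(both$consensus$sigma[ib],
               sqrt(sum(both$scaled_S[inc, q_i]^2)) / sum(inc))
})

test_that("per-dataset low-q truncation and disconnection errors work", {
  q <- seq(0.0025, 0.4, by = 0.005)
  ideal <- sphere_profile(20, 1, q)
  profs <- lapply(1:3, function(j)
    simulate_instrument(ideal, a = 1, b = 0, noise_k = 0.01, seed = 90 + j))
  grid <- qgrid(c(0, 0.4, 0.005))
  cons <- sas_combine(profs, grid, qmin = c(0.05, NA, NA))
  expect_true(all(!cons$present[1, grid$centers < 0.05]))
  # a dataset with no overlap is reported by index
  lo <- sas_profile(q[q < 0.1], ideal$I[q < 0.1], rep(0.01, sum(q < 0.1)))
  hi <- sas_profile(q[q > 0.3], ideal$I[q > 0.3], rep(0.01, sum(q > 0.3)))
  expect_error(sas_combine(list(lo, hi), grid), "disconnected|share too few")
})
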