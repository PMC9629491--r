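low_high_pair <- function(seed_lo, seed_hi, contam = NULL) {
  qlo <- seq(0.006, 0.3, by = 0.002)
  qhi <- seq(0.01, 0.5, by = 0.002)
  ideal_hi <- sphere_profile(25, 1, qhi)
  if (!is.null(contam)) ideal_hi <- do.call(contaminate, c(list(ideal_hi), contam))
  list(low = simulate_instrument(sphere_profile(25, 1, qlo), a = 1,
                                 noise_k = 0.004, floor = 0.02, seed = seed_lo),
       high = simulate_instrument(ideal_hi, a = 3, noise_k = 0.002,
                                  floor = 0.02, seed = seed_hi))
}

test_that("overlap scaling recovers exact and noisy factors", {
  q <- seq(0.008, 0.5, by = 0.002)
  p <- sphere_profile(25, 1, q)
  high <- sas_profile(p$q, p$I / 3, p$sigma / 3)
  sc <- scale_overlap(p, high, c(0.12, 0.22))
  expect_equal(sc$c, 3, tolerance = 1e-9)
  # independent noise: recovered within a few standard errors
  a <- simulate_instrument(p, noise_k = 0.01, floor = 0.02, seed = 1)
  b <- simulate_instrument(p, noise_k = 0.01, floor = 0.02, seed = 2)
  scn <- scale_overlap(a, b, c(0.1, 0.25))
  expect_lt(abs(scn$c - 1), 4 * scn$c_err)
  expect_lt(abs(scn$c - 1), 4 / sqrt(scn$n))
  # disjoint ranges are refused
  lo <- sas_profile(q[q < 0.1], p$I[q < 0.1], p$sigma[q < 0.1])
  hi <- sas_profile(q[q > 0.3], p$I[q > 0.3], p$sigma[q > 0.3])
  expect_error(scale_overlap(lo, hi, c(0.15, 0.25)), "overlap")
})

test_that("splicing reconstructs a known whole and keeps provenance", {
  q <- seq(0.008, 0.5, by = 0.002)
  p <- sphere_profile(25, 1, q)
  # merging a profile with itself is the identity
  m0 <- merge_profiles(p, p, cut_q = 0.2)
  expect_equal(m0$I, p$I)
  expect_equal(length(m0$q), length(p$q))
  # split + pre-scale by 3, remerge: original recovered
  low <- sas_profile(p$q[p$q <= 0.25], p$I[p$q <= 0.25], p$sigma[p$q <= 0.25])
  high0 <- sas_profile(p$q[p$q >= 0.1], 3 * p$I[p$q >= 0.1], 3 * p$sigma[p$q >= 0.1])
  m <- merge_profiles(low, high0, cut_q = 0.15)
  expect_equal(m$I, p$I[match(m$q, p$q)], tolerance = 1e-6)
  expect_identical(rle(m$meta$provenance)$values, c(1L, 2L))
  # every output point is an input point times its block scale
  hi_part <- m$meta$provenance == 2L
  expect_equal(m$I[hi_part],
               m$meta$scales[1] * high0$I[match(m$q[hi_part], high0$q)])
  # three-way merge partitions the q axis into three contiguous blocks
  mid <- sas_profile(p$q[p$q >= 0.08 & p$q <= 0.35],
                     2 * p$I[p$q >= 0.08 & p$q <= 0.35],
                     2 * p$sigma[p$q >= 0.08 & p$q <= 0.35])
  hi <- sas_profile(p$q[p$q >= 0.28], 5 * p$I[p$q >= 0.28], 5 * p$sigma[p$q >= 0.28])
  m3 <- merge_profiles(sas_profile(p$q[p$q <= 0.15], p$I[p$q <= 0.15],
                                   p$sigma[p$q <= 0.15]),
                       list(mid, hi), cut_q = c(0.12, 0.3))
  expect_identical(rle(m3$meta$provenance)$values, c(1L, 2L, 3L))
  expect_true(all(diff(m3$q) > 0))
  # non-overlapping plans are associative
  m12 <- merge_profiles(sas_profile(p$q[p$q <= 0.15], p$I[p$q <= 0.15],
                                    p$sigma[p$q <= 0.15]), mid, cut_q = 0.12)
  m123 <- merge_profiles(m12, hi, cut_q = 0.3)
  expect_equal(m123$I, m3$I, tolerance = 1e-12)
})

test_that("the q_min scan accepts clean concentrated data at the first candidate", {
  pair <- low_high_pair(502, 503)
  sc <- merge_scan(pair$low, pair$high, seq(0.07, 0.13, by = 0.01))
  expect_equal(sc$recommended_qmin, 0.07)
  expect_true(all(c("qmin", "Rg", "d_max", "accepted") %in% names(sc$table)))
})

test_that("the q_min scan excludes planted low-q pathologies", {
  # interference: S(q) = 1 - 0.3 exp(-(25 q)^2) deviates < 1% above q ~ 0.074
  pair <- low_high_pair(21, 23, contam = list(interference_beta = 0.3,
                                              interference_xi = 25))
  sc <- merge_scan(pair$low, pair$high, seq(0.05, 0.13, by = 0.01))
  expect_gte(sc$recommended_qmin, 0.06)
  expect_false(sc$table$accepted[1])
  # aggregate: the merged curve at the recommendation matches the clean reference
  pair2 <- low_high_pair(21, 25, contam = list(aggregate_fraction = 0.02,
                                               size_multiple = 5))
  sc2 <- merge_scan(pair2$low, pair2$high, seq(0.05, 0.13, by = 0.01))
  expect_false(is.na(sc2$recommended_qmin))
  m <- merge_profiles(pair2$low, pair2$high, cut_q = sc2$recommended_qmin,
                      qmin_high = sc2$recommended_qmin)
  g <- auto_guinier(m); gref <- auto_guinier(pair2$low)
  expect_lt(abs(g$Rg - gref$Rg) / sqrt(g$Rg_err^2 + gref$Rg_err^2), 1.5)
})
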