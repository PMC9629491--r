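test_that("the IFT reproduces the analytic sphere pair-distance distribution", {
  q <- seq(0.008, 0.35, by = 0.0025)
  p <- sphere_profile(30, 1, q)
  pr <- pr_transform(p, 60)
  expect_equal(pr$Rg, sqrt(3 / 5) * 30, tolerance = 0.01)
  expect_equal(pr$I0, 1, tolerance = 0.01)
  pan <- sphere_pr_analytic(pr$r, 30)
  expect_lt(max(abs(pr$P / max(pr$P) - pan / max(pan))), 0.02)
  # self-consistency between the stored fit and the forward transform
  expect_lt(max(abs(pr_forward(pr) - pr$fitted) /
                  pmax(abs(pr$fitted), 1e-12)), 1e-8)
  # constrained endpoints
  expect_equal(pr$P[1], 0)
  expect_equal(pr$P[length(pr$P)], 0)
})

test_that("an overextended d_max leaves a near-zero tail", {
  q <- seq(0.008, 0.35, by = 0.0025)
  obs <- simulate_instrument(sphere_profile(30, 1, q), noise_k = 0.01,
                             floor = 0.02, seed = 5)
  pr9 <- pr_transform(obs, 90)
  tail <- pr9$r >= 60
  expect_lt(max(abs(pr9$P[tail])), 0.05 * max(pr9$P))
})

test_that("the transform is linear in the intensity scale", {
  q <- seq(0.008, 0.35, by = 0.005)
  p <- sphere_profile(25, 1, q)
  pr1 <- pr_transform(p, 50)
  p7 <- sas_profile(p$q, 7 * p$I, 7 * p$sigma)
  pr7 <- pr_transform(p7, 50)
  expect_equal(pr7$P, 7 * pr1$P, tolerance = 1e-8)
  expect_equal(pr7$Rg, pr1$Rg, tolerance = 1e-10)
})

test_that("stored moments are self-consistent", {
  q <- seq(0.008, 0.35, by = 0.0025)
  pr <- pr_transform(sphere_profile(28, 2, q), 56)
  tw <- diff(range(pr$r)) / (length(pr$r) - 1)
  ip <- sum(pr$P) * tw - tw * (pr$P[1] + pr$P[length(pr$P)]) / 2
  ir2p <- sum(pr$r^2 * pr$P) * tw -
    tw * (pr$r[1]^2 * pr$P[1] + pr$r[length(pr$r)]^2 * pr$P[length(pr$P)]) / 2
  expect_equal(pr$Rg^2, ir2p / (2 * ip), tolerance = 1e-6)
  expect_equal(pr$I0, 4 * pi * ip, tolerance = 1e-6)
})

test_that("d_max refinement finds the sphere diameter", {
  q <- seq(0.008, 0.35, by = 0.0025)
  p25 <- sphere_profile(25, 1, q)
  d0 <- refine_dmax(p25, c(35, 70))
  expect_equal(as.numeric(d0), 51)      # noise-free estimate, true 2R = 50
  # under 1% noise the estimate stays in a narrow band around 2R
  ds <- vapply(1:8, function(s)
    as.numeric(refine_dmax(simulate_instrument(p25, noise_k = 0.01,
                                               seed = 200 + s),
                           c(40, 65))), numeric(1))
  expect_gte(sum(ds >= 48 & ds <= 53), 7L)
  # a pure monotone decay leaves d_max ill-determined
  pg <- guinier_law_profile(Rg = 15, I0 = 1, qmax = 0.12, dq = 0.0015,
                            sigma_rel = 0.005)
  expect_warning(refine_dmax(pg, c(30, 60)), "ill-determined|flat")
})

test_that("the released-P(0) check detects planted subtraction errors", {
  q <- seq(0.008, 0.8, by = 0.0025)
  obs <- simulate_instrument(sphere_profile(30, 1, q), noise_k = 0.01,
                             floor = 0.05, seed = 3)
  clean <- background_check(obs, 60)
  expect_false(clean$flagged)
  expect_lt(abs(clean$background), 3 * clean$background_err)
  # under-subtraction: +0.5% of I(0)
  plus <- background_check(sas_profile(obs$q, obs$I + 0.005, obs$sigma), 60)
  expect_true(plus$flagged)
  expect_lt(abs(plus$suggested_background - 0.005) / 0.005, 0.3)
  # over-subtraction recovers a negative constant
  minus <- background_check(sas_profile(obs$q, obs$I - 0.005, obs$sigma), 60)
  expect_true(minus$flagged)
  expect_lt(minus$suggested_background, 0)
  # monotone response over three planted levels
  sug <- vapply(c(0.002, 0.005, 0.01), function(c0)
    background_check(sas_profile(obs$q, obs$I + c0, obs$sigma), 60)$background,
    numeric(1))
  expect_true(all(diff(sug) > 0))
})
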