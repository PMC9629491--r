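test_that("the sphere form factor has the textbook limits and features", {
  q <- seq(0.001, 0.5, by = 0.0005)
  p <- sphere_profile(19.365, 2, q)
  # forward limit
  expect_equal(sphere_profile(19.365, 2, 1e-9)$I[1], 2, tolerance = 1e-10)
  # Guinier Rg = sqrt(3/5) R
  g <- auto_guinier(p)
  expect_equal(g$Rg, 15.0003, tolerance = 0.01 * 15)
  # first minimum at qR ~ 4.493 (root of tan x = x)
  x <- q * 19.365
  imin <- which.min(p$I[x > 3 & x < 6])
  expect_equal(x[x > 3 & x < 6][imin], 4.493, tolerance = 1e-2)
})

test_that("the ellipsoid average reduces to the sphere and has the right Rg", {
  q <- seq(0.002, 0.3, by = 0.002)
  e <- ellipsoid_profile(30, 30, 1, q)
  s <- sphere_profile(30, 1, q)
  expect_lt(max(abs(e$I - s$I) / s$I), 1e-8)
  # prolate 2:1, Rg = sqrt((2 a^2 + c^2)/5)
  e2 <- ellipsoid_profile(20, 40, 1, q)
  rg_true <- sqrt((2 * 20^2 + 40^2) / 5)
  g <- auto_guinier(e2)
  expect_equal(g$Rg, rg_true, tolerance = 0.015 * rg_true)
  # quadrature self-convergence
  e256 <- ellipsoid_profile(20, 40, 1, q, n_orient = 256)
  e512 <- ellipsoid_profile(20, 40, 1, q, n_orient = 512)
  expect_lt(max(abs(e512$I - e256$I) / pmax(e256$I, 1e-300)), 1e-6)
})

test_that("instrument simulation is an honest, seeded noise model", {
  q <- seq(0.005, 0.3, by = 0.005)
  ideal <- sphere_profile(20, 1, q)
  # zero noise: exact affine transform
  o0 <- simulate_instrument(ideal, a = 2.5, b = 0.01, noise_k = 0)
  expect_equal(o0$I, 2.5 * ideal$I + 0.01, tolerance = 1e-12)
  # reported sigma equals the generating sigma: ~68% coverage at 1 sigma
  hits <- vapply(1:400, function(s) {
    o <- simulate_instrument(ideal, a = 1.3, b = 0.002, noise_k = 0.02,
                             floor = 0.01, seed = 5000 + s)
    mean(abs(o$I - (1.3 * ideal$I + 0.002)) <= o$sigma)
  }, numeric(1))
  expect_equal(mean(hits), 0.683, tolerance = 0.015)
  # empirical vs reported sigma at one grid point over many seeds
  i40 <- vapply(1:1000, function(s)
    simulate_instrument(ideal, a = 1, noise_k = 0.02, floor = 0.01,
                        seed = s)$I[40], numeric(1))
  rep_sig <- simulate_instrument(ideal, a = 1, noise_k = 0.02, floor = 0.01,
                                 seed = 1)$sigma[40]
  expect_equal(sd(i40), rep_sig, tolerance = 0.05)
  # planted outlier replaces the clean value by the stated multiple
  oo <- simulate_instrument(ideal, a = 1, b = 0, noise_k = 0.001,
                            outlier_idx = 40L, outlier_mult = 10, seed = 8)
  expect_equal(oo$I[40] / ideal$I[40], 10, tolerance = 1e-6)
  # determinism and RNG hygiene
  x1 <- simulate_instrument(ideal, noise_k = 0.01, seed = 99)
  set.seed(123); before <- rnorm(1)
  x2 <- simulate_instrument(ideal, noise_k = 0.01, seed = 99)
  set.seed(123); after <- rnorm(1)
  expect_identical(x1$I, x2$I)
  expect_identical(before, after)
})

test_that("contamination follows the stated mixture and structure factor", {
  q <- seq(0.002, 0.3, by = 0.002)
  ideal <- sphere_profile(20, 1, q)
  # identity at zero pathology
  expect_equal(contaminate(ideal)$I, ideal$I)
  # aggregate raises the apparent Rg (I0-weighted mixture of Rg^2)
  cont <- contaminate(ideal, aggregate_fraction = 0.02, size_multiple = 5)
  expect_gt(auto_guinier(cont)$Rg, auto_guinier(ideal)$Rg)
  # interference dip: S(0) = 1 - beta
  ci <- contaminate(ideal, interference_beta = 0.3, interference_xi = 25)
  expect_equal(ci$I[1] / ideal$I[1], 1 - 0.3 * exp(-q[1]^2 * 25^2),
               tolerance = 1e-10)
  expect_lt(ci$I[1] / ideal$I[1], 0.71)
})

test_that("campaigns regenerate exactly from their seed and record the truth", {
  cfg <- campaign_config(n_instruments = 4)
  c1 <- simulate_campaign(cfg, master_seed = 77)
  c2 <- simulate_campaign(cfg, master_seed = 77)
  for (j in 1:4) {
    expect_identical(c1$profiles[[j]]$q, c2$profiles[[j]]$q)
    expect_identical(c1$profiles[[j]]$I, c2$profiles[[j]]$I)
  }
  expect_identical(c1$truth, c2$truth)
  # different seed changes the data
  c3 <- simulate_campaign(cfg, master_seed = 78)
  expect_false(identical(c1$profiles[[1]]$I, c3$profiles[[1]]$I))
  # file output round trip (byte-identical on rewrite)
  d1 <- file.path(tempdir(), "campA"); d2 <- file.path(tempdir(), "campB")
  simulate_campaign(cfg, master_seed = 77, out_dir = d1)
  simulate_campaign(cfg, master_seed = 77, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
  # truth holds what combine needs to be validated end to end
  tr <- c1$truth$instruments[[2]]
  expect_true(all(c("a", "b", "seed", "dq") %in% names(tr)))
  expect_gt(tr$a, 0)
})

test_that("combining a campaign recovers the planted affine parameters", {
  camp <- simulate_campaign(campaign_config(), master_seed = 7)
  cons <- sas_combine(camp$profiles, qgrid(c(0, 0.5, 0.005)), reference = 1)
  tr_a <- vapply(camp$truth$instruments, `[[`, numeric(1), "a")
  tr_b <- vapply(camp$truth$instruments, `[[`, numeric(1), "b")
  a_exp <- tr_a[1] / tr_a
  b_exp <- tr_b[1] - tr_a[1] * tr_b / tr_a
  expect_lt(median(abs(cons$scaling$a - a_exp) / a_exp), 0.01)
  expect_lt(max(abs(cons$scaling$b - b_exp)), 5e-4)
})
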