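# Shared fixtures: all synthetic, generated in code at test time.

# exact Guinier-law profile I = I0 exp(-q^2 Rg^2 / 3)
guinier_law_profile <- function(Rg = 15, I0 = 1, qmax = 0.3, dq = 0.002,
                                sigma_rel = 1e-6) {
  q <- seq(dq, qmax, by = dq)
  I <- I0 * exp(-q^2 * Rg^2 / 3)
  sas_profile(q, I, pmax(sigma_rel * I, 1e-300))
}

# analytic sphere pair-distance distribution, unnormalised
sphere_pr_analytic <- function(r, R) {
  ifelse(r <= 2 * R, r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3)), 0)
}

# noise-free same-grid campaign: affine copies of one ideal curve on the
# combine grid itself (rebinning is then the identity)
affine_campaign <- function(a, b, R = 20, grid = qgrid(c(0, 0.4, 0.005))) {
  ideal <- sphere_profile(R, 1, grid$centers)
  lapply(seq_along(a), function(j)
    sas_profile(grid$centers, a[j] * ideal$I + b[j],
                pmax(1e-8 * (abs(ideal$I) + 1e-3), 1e-300)))
}

# write a text file and return its path (self-deleting with the test env)
tmp_text <- function(lines, envir = parent.frame()) {
  f <- tempfile(fileext = ".dat")
  writeLines(lines, f)
  withr::defer(unlink(f), envir = envir)
  f
}
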