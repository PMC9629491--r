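# Synthetic multi-instrument campaign generator: an ideal form-factor curve
# observed through per-instrument scale factors, background offsets, distinct
# q-grids, counting-like noise, planted outliers and optional low-q
# contamination, with the full ground truth recorded so recovery can be
# tested exactly.

# run expr with a temporary RNG state seeded by `seed` (global state restored)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sphere form-factor amplitude 3(sin x - x cos x)/x^3 with the x -> 0 limit
sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 10          # series expansion
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Ideal sphere scattering profile
#'
#' Exact homogeneous-sphere form factor
#' \code{I(q) = I0 [3 (sin qR - qR cos qR) / (qR)^3]^2}, with the q -> 0
#' limit \code{I = I0} handled analytically. The curve's radius of gyration
#' is \code{sqrt(3/5) R}; its first minimum sits at \code{qR ~ 4.493}.
#' Errors are a tiny positive sentinel proportional to the local intensity
#' scale (the profile is noise-free).
#'
#' @param R sphere radius (Angstrom).
#' @param I0 forward intensity.
#' @param q momentum-transfer grid (1/Angstrom).
#' @return A \code{\link{sas_profile}} with shape metadata used by
#'   \code{\link{contaminate}}.
#' @export
sphere_profile <- function(R, I0 = 1, q) {
  stopifnot(R > 0, I0 > 0)
  I <- I0 * sphere_amplitude(q * R)^2
  sigma <- 1e-6 * (abs(I) + 1e-3 * I0)
  sas_profile(q, I, sigma,
              meta = list(label = sprintf("sphere R=%g", R),
                          shape = "sphere", R = R, I0 = I0))
}

#' Ideal ellipsoid-of-revolution scattering profile
#'
#' Orientation-averaged form factor of an ellipsoid with equatorial
#' semi-axis \code{a_semi} (twice) and polar semi-axis \code{c_semi},
#' averaged by Gauss-Legendre quadrature over the angle cosine. With
#' \code{a_semi == c_semi} it reduces to the sphere. The curve's Rg is
#' \code{sqrt((2 a^2 + c^2) / 5)}.
#'
#' @param a_semi,c_semi semi-axes (Angstrom).
#' @param I0 forward intensity.
#' @param q momentum-transfer grid (1/Angstrom).
#' @param n_orient quadrature order (default 256).
#' @return A \code{\link{sas_profile}}.
#' @export
ellipsoid_profile <- function(a_semi, c_semi, I0 = 1, q, n_orient = 256L) {
  stopifnot(a_semi > 0, c_semi > 0, I0 > 0)
  gl <- pracma::gaussLegendre(n_orient, 0, 1)
  I <- numeric(length(q))
  for (m in seq_len(n_orient)) {
    u <- gl$x[m]
    reff <- sqrt(a_semi^2 * (1 - u^2) + c_semi^2 * u^2)
    I <- I + gl$w[m] * sphere_amplitude(q * reff)^2
  }
  I <- I0 * I
  sigma <- 1e-6 * (abs(I) + 1e-3 * I0)
  sas_profile(q, I, sigma,
              meta = list(label = sprintf("ellipsoid a=%g c=%g", a_semi, c_semi),
                          shape = "ellipsoid", a_semi = a_semi,
                          c_semi = c_semi, I0 = I0))
}

#' Observe an ideal curve through one instrument
#'
#' Applies the per-instrument distortions of a multi-facility campaign:
#' \code{I_obs = a I_ideal + b + noise} with Gaussian noise of standard
#' deviation \code{sigma(q) = noise_k sqrt(a I_ideal + floor)} (counting-like,
#' with \code{floor} modelling a flat incoherent background's contribution to
#' the noise). The reported sigma column is the TRUE generating sigma, so
#' coverage is exact by construction. Planted outliers replace the clean
#' value at the given indices by \code{outlier_mult} times itself.
#'
#' @param ideal a \code{\link{sas_profile}} (typically from
#'   \code{\link{sphere_profile}}).
#' @param a multiplicative scale (> 0).
#' @param b additive background offset.
#' @param noise_k noise scale; 0 gives an exact affine transform (sigma is
#'   then a small positive sentinel).
#' @param floor flat noise-floor term inside the square root.
#' @param grid optional \code{\link{qgrid}}: the ideal curve is first
#'   re-gridded onto it (distinct instruments, distinct grids).
#' @param outlier_idx indices (after any re-gridding) to corrupt.
#' @param outlier_mult multiplier applied at \code{outlier_idx} (default 10).
#' @param seed RNG seed (global RNG state is restored afterwards).
#' @return A \code{\link{sas_profile}} with the truth in \code{meta$truth}.
#' @export
simulate_instrument <- function(ideal, a = 1, b = 0, noise_k = 0.01,
                                floor = 0, grid = NULL,
                                outlier_idx = integer(0), outlier_mult = 10,
                                seed = NULL) {
  stopifnot(inherits(ideal, "sas_profile"), a > 0, noise_k >= 0, floor >= 0)
  base <- if (is.null(grid)) ideal else rebin(ideal, grid)
  clean <- a * base$I + b
  sig <- noise_k * sqrt(pmax(a * base$I + floor, 0))
  sentinel <- 1e-9 * (abs(clean) + max(abs(clean)) * 1e-3)
  sig_rep <- pmax(sig, sentinel)
  I <- with_seed(seed, clean + if (noise_k > 0) stats::rnorm(length(clean), 0, sig) else 0)
  if (length(outlier_idx)) {
    outlier_idx <- outlier_idx[outlier_idx >= 1 & outlier_idx <= length(I)]
    I[outlier_idx] <- outlier_mult * clean[outlier_idx]
  }
  sas_profile(base$q, I, sig_rep,
              meta = list(label = ideal$meta$label,
                          truth = list(a = a, b = b, noise_k = noise_k,
                                       floor = floor,
                                       outlier_idx = outlier_idx,
                                       outlier_mult = outlier_mult,
                                       seed = seed)))
}

#' Plant low-q pathologies into an ideal curve
#'
#' Adds the two low-q failure modes screened for in consensus building:
#' a small mass fraction \code{x} of aggregate (the same shape at
#' \code{size_multiple} times the radius, forward intensity weighted by
#' volume per unit mass, i.e. \code{s^3} per mass fraction) and
#' interparticle interference modelled phenomenologically as a structure
#' factor \code{S(q) = 1 - beta exp(-q^2 xi^2)}:
#' \deqn{I = [(1 - x) I_ideal + x s^3 I_big(q)] S(q)}
#' With all pathology parameters zero this is the identity.
#'
#' @param ideal a profile created by \code{\link{sphere_profile}} (shape
#'   metadata required).
#' @param aggregate_fraction mass fraction x of aggregate, 0 <= x < 1.
#' @param size_multiple aggregate radius multiple s (default 5).
#' @param interference_beta interference depth beta < 1 (S(0) = 1 - beta).
#' @param interference_xi interference length xi (Angstrom).
#' @return A \code{\link{sas_profile}} with contamination recorded in meta.
#' @export
contaminate <- function(ideal, aggregate_fraction = 0, size_multiple = 5,
                        interference_beta = 0, interference_xi = 25) {
  stopifnot(inherits(ideal, "sas_profile"),
            aggregate_fraction >= 0, aggregate_fraction < 1,
            interference_beta < 1)
  x <- aggregate_fraction; s <- size_multiple
  I <- ideal$I
  if (x > 0) {
    if (is.null(ideal$meta$shape) || ideal$meta$shape != "sphere")
      stop("contaminate needs a sphere profile with shape metadata")
    big <- sphere_profile(s * ideal$meta$R, ideal$meta$I0, ideal$q)
    I <- (1 - x) * I + x * s^3 * big$I
  }
  if (interference_beta != 0)
    I <- I * (1 - interference_beta * exp(-ideal$q^2 * interference_xi^2))
  meta <- ideal$meta
  meta$contamination <- list(aggregate_fraction = x, size_multiple = s,
                             interference_beta = interference_beta,
                             interference_xi = interference_xi)
  sas_profile(ideal$q, I, pmax(ideal$sigma, 1e-12 * max(abs(I))), meta = meta)
}

#' Default campaign configuration
#'
#' Conditions emulating a multi-facility round-robin on a small globular
#' protein: 8 instruments, per-instrument scales spread over about a decade
#' (arbitrary detector units), background offsets within a few tenths of a
#' percent of the scaled forward intensity (residual solvent-subtraction
#' error), counting-like noise of about 1 percent of I(0)^(1/2) units, and
#' per-instrument q-ranges and spacings that differ but overlap.
#'
#' @param n_instruments number of datasets (default 8).
#' @param R sphere radius (default 20 Angstrom, Rg about 15.5).
#' @param I0 forward intensity (default 1).
#' @param noise_k noise scale (default 0.01: about 1 percent relative error
#'   at low q for I0 = 1).
#' @return A list accepted by \code{\link{simulate_campaign}}.
#' @export
campaign_config <- function(n_instruments = 8L, R = 20, I0 = 1,
                            noise_k = 0.01) {
  list(n_instruments = n_instruments, shape = "sphere", R = R, I0 = I0,
       a_range = c(0.5, 5), b_frac_range = c(-0.003, 0.003),
       noise_k = noise_k, floor = 0,
       qmin_range = c(0.006, 0.015), qmax_range = c(0.35, 0.5),
       dq_range = c(0.001, 0.003),
       outliers = NULL, contamination = NULL)
}

#' Simulate a multi-instrument campaign
#'
#' Draws per-instrument distortion parameters from the configuration ranges
#' and observes one ideal curve through each instrument. Everything is
#' derived deterministically from \code{master_seed}; rerunning with the same
#' config and seed regenerates the campaign exactly, and the returned truth
#' record holds every drawn value.
#'
#' @param config list from \code{\link{campaign_config}} (fields may be
#'   overridden). \code{outliers} may be a list
#'   \code{list(instrument =, idx =, mult =)}; \code{contamination} a list
#'   \code{list(instrument =, aggregate_fraction =, size_multiple =,
#'   interference_beta =, interference_xi =)}.
#' @param master_seed integer master seed.
#' @param out_dir optional directory: writes one \code{.dat} file per
#'   instrument plus \code{truth.json}.
#' @return List with \code{profiles} (list of \code{\link{sas_profile}}) and
#'   \code{truth} (per-instrument a, b, grids, seeds, plants).
#' @export
simulate_campaign <- function(config = campaign_config(), master_seed = 1L,
                              out_dir = NULL) {
  stopifnot(config$n_instruments >= 2L)
  N <- config$n_instruments
  pars <- with_seed(master_seed, {
    list(a = exp(stats::runif(N, log(config$a_range[1]), log(config$a_range[2]))),
         b_frac = stats::runif(N, config$b_frac_range[1], config$b_frac_range[2]),
         qmin = stats::runif(N, config$qmin_range[1], config$qmin_range[2]),
         qmax = stats::runif(N, config$qmax_range[1], config$qmax_range[2]),
         dq = stats::runif(N, config$dq_range[1], config$dq_range[2]))
  })
  seeds <- (master_seed %% 100000L) + 7919L * seq_len(N)   # < 2^31 always
  qfine <- seq(min(pars$qmin) / 2, max(pars$qmax), length.out = 3000L)
  ideal <- sphere_profile(config$R, config$I0, qfine)
  profiles <- vector("list", N)
  truth_inst <- vector("list", N)
  for (j in seq_len(N)) {
    idl <- ideal
    cont <- config$contamination
    if (!is.null(cont) && j %in% cont$instrument)
      idl <- contaminate(ideal,
                         aggregate_fraction = cont$aggregate_fraction %||% 0,
                         size_multiple = cont$size_multiple %||% 5,
                         interference_beta = cont$interference_beta %||% 0,
                         interference_xi = cont$interference_xi %||% 25)
    qj <- seq(pars$qmin[j], pars$qmax[j], by = pars$dq[j])
    idl_j <- sas_profile(qj, stats::approx(idl$q, idl$I, xout = qj)$y,
                         rep(1e-9 * config$I0, length(qj)), meta = idl$meta)
    b_j <- pars$b_frac[j] * pars$a[j] * config$I0
    oi <- integer(0); om <- 10
    if (!is.null(config$outliers) && j %in% config$outliers$instrument) {
      oi <- config$outliers$idx; om <- config$outliers$mult %||% 10
    }
    profiles[[j]] <- simulate_instrument(idl_j, a = pars$a[j], b = b_j,
                                         noise_k = config$noise_k,
                                         floor = config$floor,
                                         outlier_idx = oi, outlier_mult = om,
                                         seed = seeds[j])
    profiles[[j]]$meta$label <- sprintf("instrument_%02d", j)
    truth_inst[[j]] <- list(a = pars$a[j], b = b_j, qmin = pars$qmin[j],
                            qmax = pars$qmax[j], dq = pars$dq[j],
                            seed = seeds[j], outlier_idx = oi,
                            outlier_mult = om,
                            contaminated = !is.null(config$contamination) &&
                              j %in% config$contamination$instrument)
  }
  truth <- list(shape = config$shape, R = config$R, I0 = config$I0,
                Rg = sqrt(3 / 5) * config$R, noise_k = config$noise_k,
                master_seed = master_seed, instruments = truth_inst)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (j in seq_len(N))
      write_profile(profiles[[j]],
                    file.path(out_dir, sprintf("instrument_%02d.dat", j)))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
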