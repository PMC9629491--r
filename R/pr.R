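# Regularised indirect Fourier transform: the pair-distance distribution
# P(r) is expanded in a sine series P(r) = sum_k c_k sin(k pi r / dmax)
# (which enforces P(0) = P(dmax) = 0) and the coefficients minimise
# chi^2 + alpha * integral(P'')^2. The forward map is the standard Debye
# relation I(q) = 4 pi * integral_0^dmax P(r) sin(qr)/(qr) dr.

# trapezoid weights on a uniform-or-not grid
trapz_weights <- function(r) {
  n <- length(r)
  w <- numeric(n)
  w[1] <- (r[2] - r[1]) / 2
  w[n] <- (r[n] - r[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / 2
  w
}

# Basis matrices on the r grid: values, second derivatives, and values at
# r = 0 for each basis function. Sine terms vanish at 0 and dmax; the
# released-P(0) variant appends quarter-wave cosines, nonzero at r = 0 but
# still zero at dmax.
pr_basis <- function(r, d_max, K, release_p0 = FALSE, n_release = 3L) {
  ks <- seq_len(K)
  S <- sapply(ks, function(k) sin(k * pi * r / d_max))
  S2 <- sapply(ks, function(k) -(k * pi / d_max)^2 * sin(k * pi * r / d_max))
  at0 <- rep(0, K)
  dS_at_dmax <- (ks * pi / d_max) * cos(ks * pi)   # slope of each term at dmax
  if (release_p0) {
    ms <- seq_len(n_release)
    nu <- (2 * ms - 1) / 2                          # quarter-wave numbers
    C <- sapply(ms, function(m) cos(nu[m] * pi * r / d_max))
    C2 <- sapply(ms, function(m) -(nu[m] * pi / d_max)^2 * cos(nu[m] * pi * r / d_max))
    S <- cbind(S, C); S2 <- cbind(S2, C2)
    at0 <- c(at0, rep(1, n_release))
    dS_at_dmax <- c(dS_at_dmax, -(nu * pi / d_max) * sin(nu * pi))
  }
  list(S = S, S2 = S2, at0 = at0, d_at_dmax = dS_at_dmax)
}

# forward-transform design matrix: A[i, k] = 4 pi * sum_l w_l K(q_i, r_l) S[l, k]
pr_design <- function(q, r, S) {
  w <- trapz_weights(r)
  qr <- outer(q, r)
  Kq <- ifelse(qr == 0, 1, sin(qr) / ifelse(qr == 0, 1, qr))
  4 * pi * (Kq %*% (w * S))
}

pr_solve <- function(A, y, sig, B, alpha) {
  Wh <- 1 / sig
  Aw <- A * Wh
  yw <- y * Wh
  G <- crossprod(Aw)
  M <- G + alpha * B
  c_hat <- tryCatch(solve(M, crossprod(Aw, yw)),
                    error = function(e) NULL)
  tries <- 0
  while (is.null(c_hat) && tries < 12) {
    alpha <- alpha * 10; tries <- tries + 1
    M <- G + alpha * B
    c_hat <- tryCatch(solve(M, crossprod(Aw, yw)), error = function(e) NULL)
  }
  if (is.null(c_hat)) stop("singular IFT normal equations even after raising alpha")
  if (tries > 0) warning("singular IFT normal equations: alpha raised to ", alpha)
  Minv <- solve(M)
  list(c = drop(c_hat), cov = Minv %*% G %*% Minv, alpha = alpha,
       resid2 = sum((yw - Aw %*% c_hat)^2),
       penalty = drop(crossprod(c_hat, B %*% c_hat)))
}

# L-curve corner: maximum curvature of (log residual norm, log penalty norm)
pr_lcurve_alpha <- function(A, y, sig, B, n_alpha = 25) {
  G <- crossprod(A / sig)
  scale0 <- sum(diag(G)) / max(sum(diag(B)), .Machine$double.eps)
  alphas <- scale0 * 10^seq(-8, 4, length.out = n_alpha)
  rho <- eta <- rep(NA_real_, n_alpha)
  for (i in seq_along(alphas)) {
    s <- tryCatch(pr_solve(A, y, sig, B, alphas[i]), error = function(e) NULL)
    if (is.null(s)) next
    rho[i] <- log(max(s$resid2, 1e-300))
    eta[i] <- log(max(s$penalty, 1e-300))
  }
  ok <- which(is.finite(rho) & is.finite(eta))
  if (length(ok) < 5) return(alphas[stats::median(ok)])
  x <- rho[ok]; z <- eta[ok]
  # curvature by centred finite differences in the parameterisation index
  k <- rep(-Inf, length(ok))
  for (i in 2:(length(ok) - 1)) {
    x1 <- (x[i + 1] - x[i - 1]) / 2; z1 <- (z[i + 1] - z[i - 1]) / 2
    x2 <- x[i + 1] - 2 * x[i] + x[i - 1]; z2 <- z[i + 1] - 2 * z[i] + z[i - 1]
    den <- (x1^2 + z1^2)^1.5
    if (den > 0) k[i] <- (x1 * z2 - z1 * x2) / den
  }
  alphas[ok][which.max(k)]
}

#' Indirect Fourier transform: P(r) from I(q)
#'
#' Computes the pair-distance distribution P(r) on \code{[0, d_max]} by
#' expanding P in a smooth sine basis (\code{K = ceiling(q_max d_max / pi) + 4}
#' terms, a Shannon-channel count) and minimising
#' \code{chi^2 + alpha * integral (P'')^2 dr}. The sine basis enforces
#' \code{P(0) = P(d_max) = 0}; with \code{constrain_p0 = FALSE} quarter-wave
#' cosine terms are added so that P(0) is free (used by the
#' solvent-subtraction check, \code{\link{background_check}}).
#'
#' Rg and I(0) are evaluated from the moments of P(r):
#' \code{Rg^2 = integral(r^2 P) / (2 integral(P))},
#' \code{I(0) = 4 pi integral(P)}.
#'
#' @param profile a \code{\link{sas_profile}} with at least 20 points.
#' @param d_max maximum particle dimension (Angstrom).
#' @param alpha regularisation weight, or \code{"auto"} for L-curve corner
#'   selection.
#' @param constrain_p0 enforce P(0) = 0 (default TRUE).
#' @param n_r number of r-grid points (default 201).
#' @param fit_background also fit a flat additive intensity background jointly
#'   with P(r); its value is returned as \code{background}.
#' @return An object of class \code{"sas_pr"}: \code{r}, \code{P},
#'   \code{P_err}, \code{d_max}, \code{Rg}, \code{Rg_err}, \code{I0},
#'   \code{alpha}, \code{fitted} (fitted I on the input q), \code{chi2_reduced},
#'   \code{p0_constrained}, \code{p0}, \code{p0_err}, \code{background},
#'   \code{coefficients}, plus internals used by \code{\link{pr_forward}}.
#' @examples
#' q <- seq(0.01, 0.35, by = 0.005)
#' p <- sphere_profile(R = 30, I0 = 1, q = q)
#' pr <- pr_transform(p, d_max = 60)
#' print(pr)
#' @export
pr_transform <- function(profile, d_max, alpha = "auto", constrain_p0 = TRUE,
                         n_r = 201L, fit_background = FALSE) {
  stopifnot(inherits(profile, "sas_profile"), d_max > 0)
  if (length(profile$q) < 20L) stop("need at least 20 data points for the IFT")
  q_max <- max(profile$q)
  if (d_max < pi / q_max)
    warning("d_max below the resolution sanity bound pi/q_max = ",
            signif(pi / q_max, 3))
  r <- seq(0, d_max, length.out = n_r)
  K <- ceiling(q_max * d_max / pi) + 4L
  bs <- pr_basis(r, d_max, K, release_p0 = !constrain_p0)
  A <- pr_design(profile$q, r, bs$S)
  nb <- ncol(bs$S)
  if (fit_background) {
    A <- cbind(A, 1)
    bs$S <- cbind(bs$S, 0)   # background does not contribute to P(r)
    bs$S2 <- cbind(bs$S2, 0)
    bs$at0 <- c(bs$at0, 0)
    bs$d_at_dmax <- c(bs$d_at_dmax, 0)
  }
  tw <- trapz_weights(r)
  B <- crossprod(bs$S2 * sqrt(tw))          # integral (P'')^2 in coefficients
  if (fit_background) B[nrow(B), ncol(B)] <- 0
  if (identical(alpha, "auto"))
    alpha <- pr_lcurve_alpha(A, profile$I, profile$sigma, B)
  sol <- pr_solve(A, profile$I, profile$sigma, B, alpha)
  cc <- sol$c
  P <- drop(bs$S %*% cc)
  P_err <- sqrt(pmax(rowSums((bs$S %*% sol$cov) * bs$S), 0))
  fitted <- drop(A %*% cc)
  n <- length(profile$q)
  chi2_red <- sum(((profile$I - fitted) / profile$sigma)^2) / max(n - nb, 1)
  ip <- sum(tw * P)
  ir2p <- sum(tw * r^2 * P)
  Rg <- sqrt(max(ir2p / (2 * ip), 0))
  # first-order error on Rg from coefficient covariance
  m0 <- colSums(tw * bs$S); m2 <- colSums(tw * r^2 * bs$S)
  gr <- (m2 - (ir2p / ip) * m0) / (2 * ip) / (2 * Rg)
  Rg_err <- sqrt(max(drop(t(gr) %*% sol$cov %*% gr), 0))
  p0 <- sum(bs$at0 * cc)
  p0_err <- sqrt(max(drop(t(bs$at0) %*% sol$cov %*% bs$at0), 0))
  structure(list(r = r, P = P, P_err = P_err, d_max = d_max,
                 Rg = Rg, Rg_err = Rg_err, I0 = 4 * pi * ip,
                 alpha = sol$alpha, fitted = fitted,
                 chi2_reduced = chi2_red, p0_constrained = constrain_p0,
                 p0 = p0, p0_err = p0_err,
                 background = if (fit_background) cc[length(cc)] else 0,
                 dP_at_dmax = sum(bs$d_at_dmax * cc),
                 coefficients = cc, basis = bs, q = profile$q,
                 cov = sol$cov),
            class = "sas_pr")
}

#' Forward transform of a P(r) result back to I(q)
#'
#' Evaluates \code{I(q) = 4 pi integral P(r) sin(qr)/(qr) dr} with the same
#' quadrature used in the fit; on the fitted q values this reproduces
#' \code{x$fitted}.
#'
#' @param x a \code{"sas_pr"} object.
#' @param q momentum-transfer values (default: the fitted q grid).
#' @return Numeric vector of intensities (plus the fitted background, if any).
#' @export
pr_forward <- function(x, q = x$q) {
  stopifnot(inherits(x, "sas_pr"))
  A <- pr_design(q, x$r, x$basis$S)
  drop(A %*% x$coefficients)
}

#' @export
print.sas_pr <- function(x, ...) {
  cat(sprintf("P(r) transform: d_max = %g A, %d r-points, alpha = %.3g\n",
              x$d_max, length(x$r), x$alpha))
  cat(sprintf("  Rg = %.3f +/- %.3f A, I(0) = %.5g, reduced chi^2 = %.4g\n",
              x$Rg, x$Rg_err, x$I0, x$chi2_reduced))
  if (!x$p0_constrained)
    cat(sprintf("  released P(0) = %.4g +/- %.2g\n", x$p0, x$p0_err))
  if (x$background != 0)
    cat(sprintf("  fitted flat background = %.4g\n", x$background))
  invisible(x)
}

#' @export
plot.sas_pr <- function(x, ...) {
  graphics::plot(x$r, x$P, type = "l", xlab = "r (A)", ylab = "P(r)", ...)
  graphics::arrows(x$r, x$P - x$P_err, x$r, x$P + x$P_err,
                   length = 0, col = "grey60")
  graphics::lines(x$r, x$P)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
fitted.sas_pr <- function(object, ...) object$fitted

#' @export
coef.sas_pr <- function(object, ...) object$coefficients

#' Refine the maximum dimension d_max
#'
#' Scans integer d_max candidates over \code{d_range} and scores each P(r)
#' solution for (i) failure to approach d_max as a horizontal tangent
#' (\code{|P'(d_max)| d_max / max(P)}: large when the r-range is truncated),
#' (ii) significantly negative P anywhere (below -3 sigma: interference-like
#' artefacts), and (iii) a long essentially-zero tail (overextension). The
#' smallest candidate whose score is within a small tolerance of the minimum
#' is returned, matching the convention of reporting d_max in whole Angstrom.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param d_range length-2 numeric range bracketing the plausible d_max.
#' @param alpha regularisation weight passed to \code{\link{pr_transform}}.
#' @param tol relative score tolerance for the "smallest minimiser" rule
#'   (default 0.10).
#' @return Integer d_max (Angstrom), with the scan table in attribute
#'   \code{"scan"} and a warning if no candidate keeps P above -3 sigma.
#' @export
refine_dmax <- function(profile, d_range, alpha = "auto", tol = 0.10) {
  stopifnot(length(d_range) == 2L, d_range[1] > 0, d_range[2] > d_range[1])
  cands <- seq.int(ceiling(d_range[1]), floor(d_range[2]))
  if (!length(cands)) stop("d_range brackets no integer candidate")
  score <- neg <- tailf <- slope <- rep(NA_real_, length(cands))
  for (i in seq_along(cands)) {
    pr <- tryCatch(pr_transform(profile, cands[i], alpha = alpha),
                   error = function(e) NULL)
    if (is.null(pr)) next
    pmax_ <- max(pr$P)
    if (pmax_ <= 0) next
    # horizontal-tangent term: mean |P'| over the last 5% of the r range
    # (averaging over a short terminal arc is robust against the boundary
    # wiggle that the exact endpoint derivative picks up)
    i5 <- which(pr$r >= 0.95 * pr$d_max)
    dP <- diff(pr$P) / diff(pr$r)
    s_trunc <- mean(abs(dP[i5[-length(i5)]])) * pr$d_max / pmax_
    has_neg <- any(pr$P < -3 * pr$P_err - 1e-12 * pmax_)
    # dead tail: contiguous end region where |P| stays below 2% of the peak
    below <- abs(pr$P) < 0.02 * pmax_
    run <- 0L
    for (l in rev(seq_along(below))) { if (below[l]) run <- run + 1L else break }
    tail_frac <- run / length(pr$P)
    slope[i] <- s_trunc; neg[i] <- as.numeric(has_neg); tailf[i] <- tail_frac
    score[i] <- s_trunc + 10 * has_neg + 3 * tail_frac
  }
  if (all(is.na(score))) stop("P(r) failed for every d_max candidate")
  if (all(neg[!is.na(neg)] > 0))
    warning("P(r) dips below -3 sigma for every candidate d_max ",
            "(aggregation or interference suspected)")
  # smallest candidate within a near-tie band of the minimum: d_max is
  # conventionally the smallest dimension consistent with the data, and the
  # terminal-arc score differentiates poorly among slightly overextended fits
  smin <- min(score, na.rm = TRUE)
  pick <- which(!is.na(score) & score <= smin + tol * smin + 0.05)[1]
  # resolution guard: fewer than ~3 Shannon channels across the selected
  # support means the data cannot localise d_max (featureless decay /
  # Guinier-only measurement)
  if (max(profile$q) * cands[pick] / pi < 3)
    warning("d_max is ill-determined: only ",
            signif(max(profile$q) * cands[pick] / pi, 2),
            " Shannon channels across the fitted r range ",
            "(featureless monotone decay or too-short q range)")
  structure(cands[pick],
            scan = data.frame(d_max = cands, score = score,
                              tangent = slope, negative = neg,
                              tail_fraction = tailf))
}

#' Solvent-subtraction check by releasing the P(0) = 0 constraint
#'
#' Fits P(r) with and without the P(0) = 0 constraint and estimates a flat
#' additive intensity constant jointly with the constrained P(r). The joint
#' constant is bias-corrected for the smoothing prior (see Details) and a
#' solvent-subtraction error is flagged when the released fit improves the
#' reduced chi-square by more than \code{chi2_gain} (default 10 percent) or
#' the corrected constant differs from zero by more than 3 of its standard
#' errors. When flagged, the constant is returned as the suggested
#' subtraction adjustment (positive: un-subtracted background remains;
#' negative: over-subtraction); otherwise the suggestion is 0.
#'
#' The check needs data reaching high q relative to the particle size
#' (several Shannon channels, \code{q_max d_max / pi}): over a short q-window
#' a flat constant is nearly degenerate with a finite-support P(r).
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param d_max maximum dimension (Angstrom).
#' @param alpha regularisation weight (default \code{"auto"}).
#' @param chi2_gain relative chi-square improvement treated as significant
#'   (default 0.10).
#' @return List of class \code{"sas_bgcheck"}: \code{suggested_background}
#'   (0 unless flagged), \code{background}, \code{background_err} (the
#'   bias-corrected constant and its error), \code{flagged}, \code{p0},
#'   \code{p0_err} (released-fit P(0)), \code{chi2_constrained},
#'   \code{chi2_released}.
#' @export
background_check <- function(profile, d_max, alpha = "auto", chi2_gain = 0.10) {
  con <- pr_transform(profile, d_max, alpha = alpha, constrain_p0 = TRUE)
  rel <- pr_transform(profile, d_max, alpha = con$alpha, constrain_p0 = FALSE)
  gain <- (con$chi2_reduced - rel$chi2_reduced) / max(con$chi2_reduced, 1e-12)

  # Bias-corrected joint constant. The regularised joint estimator of a flat
  # background is linear in the data, c_hat = g'y, and carries a bias g'y0
  # from the smoothing of P itself (on clean sphere data the raw c_hat is
  # several statistical sigma from zero). Correct it by applying the same
  # estimator to the fitted background-free curve y0 and normalising by the
  # estimator's response to a unit constant, iterating the surrogate once
  # the constant estimate stabilises: c = (g'y - g'y0) / g'1.
  q <- profile$q; y <- profile$I; sig <- profile$sigma
  r <- con$r
  K <- length(con$coefficients)
  bs <- pr_basis(r, d_max, K)
  A <- pr_design(q, r, bs$S)
  tw <- trapz_weights(r)
  Bc <- crossprod(bs$S2 * sqrt(tw))
  Wh <- 1 / sig
  Mc <- crossprod(A * Wh) + con$alpha * Bc
  Hc <- A %*% solve(Mc, t(A * Wh^2))        # y0 = Hc %*% y (constrained fit)
  Aj <- cbind(A, 1)
  Bj <- rbind(cbind(Bc, 0), 0)
  Mj <- crossprod(Aj * Wh) + con$alpha * Bj
  g <- drop(solve(Mj)[K + 1L, ] %*% t(Aj * Wh^2))
  gamma <- sum(g)                            # response of c_hat to I -> I + 1
  c_est <- sum(g * y)
  for (it in 1:4) {
    y0 <- drop(Hc %*% (y - c_est))
    c_new <- (sum(g * y) - sum(g * y0)) / gamma
    if (abs(c_new - c_est) < 1e-12 * max(abs(c_new), 1e-30)) { c_est <- c_new; break }
    c_est <- c_new
  }
  c_err <- sqrt(sum(g^2 * sig^2)) / abs(gamma)

  flagged <- gain > chi2_gain || abs(c_est) > 3 * c_err
  structure(list(suggested_background = if (flagged) c_est else 0,
                 background = c_est, background_err = c_err,
                 flagged = flagged,
                 p0 = rel$p0, p0_err = rel$p0_err,
                 chi2_constrained = con$chi2_reduced,
                 chi2_released = rel$chi2_reduced),
            class = "sas_bgcheck")
}

#' @export
print.sas_bgcheck <- function(x, ...) {
  cat(sprintf("P(0)-release subtraction check: %s\n",
              if (x$flagged) "FLAGGED (possible solvent-subtraction error)"
              else "no significant difference"))
  cat(sprintf("  released P(0) = %.4g +/- %.2g; reduced chi^2 %.4g -> %.4g\n",
              x$p0, x$p0_err, x$chi2_constrained, x$chi2_released))
  cat(sprintf("  suggested background adjustment: %.4g\n",
              x$suggested_background))
  invisible(x)
}
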