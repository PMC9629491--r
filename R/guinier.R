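#' Guinier fit over a fixed window
#'
#' Weighted least-squares fit of \code{ln I} against \code{q^2} over the
#' window \code{[i_min, i_max]}, with weights \code{(I/sigma)^2} (the
#' first-order variance of \code{ln I} is \code{(sigma/I)^2}). In the Guinier
#' regime \code{I(q) = I(0) exp(-q^2 Rg^2 / 3)}, so \code{Rg = sqrt(-3 slope)}
#' and \code{I(0) = exp(intercept)}; errors follow from the fit covariance by
#' first-order propagation. The Pearson correlation of \code{(q^2, ln I)} over
#' the window is computed unweighted.
#'
#' Points with \code{I <= 0} inside the window are excluded; a non-negative
#' slope yields an invalid (flagged, not error) fit.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param i_min,i_max first and last point indices of the fit window.
#' @param qmax_rg_limit validity bound on \code{q_max * Rg} (default 1.3).
#' @return An object of class \code{"guinier_fit"}: \code{Rg}, \code{Rg_err},
#'   \code{I0}, \code{I0_err}, \code{window} (index range), \code{q_range},
#'   \code{n_points}, \code{qmin_Rg}, \code{qmax_Rg}, \code{pearson_r},
#'   \code{valid}, \code{reason}.
#' @examples
#' q <- seq(0.005, 0.12, by = 0.0025)
#' p <- sas_profile(q, exp(-q^2 * 15^2 / 3), rep(1e-4, length(q)))
#' guinier_fit(p, 1, length(q))
#' @export
guinier_fit <- function(profile, i_min = 1L, i_max = length(profile$q),
                        qmax_rg_limit = 1.3) {
  stopifnot(inherits(profile, "sas_profile"),
            i_min >= 1L, i_max <= length(profile$q), i_min < i_max)
  idx <- seq.int(i_min, i_max)
  pos <- idx[profile$I[idx] > 0]
  if (length(pos) < 5L)
    stop("Guinier window has fewer than 5 points with positive intensity")
  q2 <- profile$q[pos]^2
  y <- log(profile$I[pos])
  w <- (profile$I[pos] / profile$sigma[pos])^2
  fit <- stats::lm.wfit(cbind(1, q2), y, w)
  slope <- unname(fit$coefficients[2]); icpt <- unname(fit$coefficients[1])
  r <- stats::cor(q2, y)
  # covariance of WLS coefficients with known weights: (X'WX)^-1
  XtWX <- crossprod(cbind(1, q2) * sqrt(w))
  cv <- tryCatch(solve(XtWX), error = function(e) matrix(NA, 2, 2))
  out <- list(Rg = NA_real_, Rg_err = NA_real_,
              I0 = exp(icpt), I0_err = exp(icpt) * sqrt(cv[1, 1]),
              window = c(i_min, i_max),
              q_range = range(profile$q[pos]),
              n_points = length(pos),
              qmin_Rg = NA_real_, qmax_Rg = NA_real_,
              pearson_r = r, valid = FALSE, reason = "")
  if (!is.finite(slope) || slope >= 0) {
    out$reason <- "non-negative Guinier slope"
    class(out) <- "guinier_fit"
    return(out)
  }
  Rg <- sqrt(-3 * slope)
  out$Rg <- Rg
  out$Rg_err <- sqrt(cv[2, 2]) * 3 / (2 * Rg)   # dRg/dslope = -3/(2 Rg)
  out$qmin_Rg <- out$q_range[1] * Rg
  out$qmax_Rg <- out$q_range[2] * Rg
  out$valid <- out$qmax_Rg <= qmax_rg_limit + 1e-9
  if (!out$valid) out$reason <- "q_max * Rg exceeds limit"
  class(out) <- "guinier_fit"
  out
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f +/- %.3f A, I(0) = %.4g +/- %.2g\n",
              x$Rg, x$Rg_err, x$I0, x$I0_err))
  cat(sprintf("  window: points %d..%d (q = %.4g..%.4g), n = %d\n",
              x$window[1], x$window[2], x$q_range[1], x$q_range[2],
              x$n_points))
  cat(sprintf("  qmin*Rg = %.3f, qmax*Rg = %.3f, Pearson r = %.5f%s\n",
              x$qmin_Rg, x$qmax_Rg, x$pearson_r,
              if (x$valid) "" else paste0("  [INVALID: ", x$reason, "]")))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) {
  c(Rg = object$Rg, I0 = object$I0)
}

#' @export
plot.guinier_fit <- function(x, profile, ...) {
  stopifnot(inherits(profile, "sas_profile"))
  sel <- profile$I > 0 & profile$q * x$Rg < 2
  graphics::plot(profile$q[sel]^2, log(profile$I[sel]),
                 xlab = expression(q^2), ylab = "ln I(q)", ...)
  graphics::abline(log(x$I0), -x$Rg^2 / 3, col = "red3")
  graphics::abline(v = x$q_range^2, lty = 3)
  invisible(x)
}

#' Automatic Guinier window selection
#'
#' Searches contiguous low-q windows for the Guinier fit whose extent is
#' self-consistent with its own Rg: \code{q_max * Rg <= qmax_rg_limit}
#' (conventionally 1.3 for globular particles) and
#' \code{q_min * Rg <= qmin_rg_limit} (avoiding fits confined to the flat
#' top). Among candidate windows with at least \code{min_points} points and
#' Pearson \code{|r| >= r_limit}, the longest is returned; ties go to the
#' window starting at the smallest q. Deterministic for fixed input.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param qmax_rg_limit upper bound on \code{q_max * Rg} (default 1.3).
#' @param qmin_rg_limit upper bound on \code{q_min * Rg} (default 0.65).
#' @param min_points minimum window length (default 10).
#' @param r_limit minimum |Pearson r| of the window (default 0.99).
#' @return A \code{"guinier_fit"} (see \code{\link{guinier_fit}}); if no
#'   admissible window exists, an invalid fit with a diagnostic
#'   \code{reason} (possible aggregation, interference or truncated data).
#' @export
auto_guinier <- function(profile, qmax_rg_limit = 1.3, qmin_rg_limit = 0.65,
                         min_points = 10L, r_limit = 0.99) {
  stopifnot(inherits(profile, "sas_profile"))
  n <- length(profile$q)
  if (n < min_points)
    stop("profile has fewer than min_points = ", min_points, " points")
  # restrict to the initial run of positive intensities (the Guinier regime
  # lies at low q, before subtracted data can dip below zero)
  npos <- if (any(profile$I <= 0)) which(profile$I <= 0)[1] - 1L else n
  if (npos < min_points) {
    out <- list(Rg = NA_real_, Rg_err = NA_real_, I0 = NA_real_,
                I0_err = NA_real_, window = c(NA_integer_, NA_integer_),
                q_range = c(NA_real_, NA_real_), n_points = 0L,
                qmin_Rg = NA_real_, qmax_Rg = NA_real_,
                pearson_r = NA_real_, valid = FALSE,
                reason = "too few positive low-q intensities")
    class(out) <- "guinier_fit"
    return(out)
  }
  # coarse Rg estimate to bound the search region
  i_hi_max <- npos
  est <- tryCatch(guinier_fit(profile, 1L, min(npos, max(min_points, 15L)),
                              qmax_rg_limit = Inf),
                  error = function(e) NULL)
  if (!is.null(est) && is.finite(est$Rg))
    i_hi_max <- max(min_points, findInterval(2.0 / est$Rg, profile$q) + 1L)
  i_hi_max <- min(i_hi_max, npos, 500L)

  # prefix sums for O(1) weighted regression and unweighted correlation over
  # any window [i0, i1]
  x <- profile$q[1:i_hi_max]^2
  y <- log(profile$I[1:i_hi_max])
  w <- (profile$I[1:i_hi_max] / profile$sigma[1:i_hi_max])^2
  cs <- function(v) c(0, cumsum(v))
  Pw <- cs(w); Pwx <- cs(w * x); Pwy <- cs(w * y)
  Pwxx <- cs(w * x^2); Pwxy <- cs(w * x * y); Pwyy <- cs(w * y^2)
  P1 <- cs(rep(1, i_hi_max)); Px <- cs(x); Py <- cs(y)
  Pxx <- cs(x^2); Pyy <- cs(y^2); Pxy <- cs(x * y)

  # selection: among windows meeting the self-consistency, length and |r|
  # constraints, prefer the longest whose weighted linear fit is statistically
  # adequate (reduced chi^2 <= chi2_adequate given the reported sigmas; a
  # lack-of-fit guard against fitting systematic curvature). If none is
  # adequate -- ideal noise-free curves resolve curvature at any window --
  # fall back to the most adequate admissible window.
  chi2_adequate <- 1.5
  best <- NULL        # best adequate (longest)
  best_fb <- NULL     # fallback: minimal reduced chi^2
  for (i1 in seq.int(min_points, i_hi_max)) {
    i0 <- seq.int(1L, i1 - min_points + 1L)
    lo <- i0; hi <- i1 + 1L
    sw <- Pw[hi] - Pw[lo]; swx <- Pwx[hi] - Pwx[lo]; swy <- Pwy[hi] - Pwy[lo]
    swxx <- Pwxx[hi] - Pwxx[lo]; swxy <- Pwxy[hi] - Pwxy[lo]
    swyy <- Pwyy[hi] - Pwyy[lo]
    det <- sw * swxx - swx^2
    slope <- (sw * swxy - swx * swy) / det
    icpt <- (swxx * swy - swx * swxy) / det
    ok <- is.finite(slope) & slope < 0
    Rg <- sqrt(pmax(-3 * slope, 0))
    qmaxRg <- profile$q[i1] * Rg
    qminRg <- profile$q[i0] * Rg
    ok <- ok & qmaxRg <= qmax_rg_limit + 1e-9 & qminRg <= qmin_rg_limit + 1e-9
    if (any(ok)) {
      m <- P1[hi] - P1[lo]
      sx <- Px[hi] - Px[lo]; sy <- Py[hi] - Py[lo]
      sxx <- Pxx[hi] - Pxx[lo]; syy <- Pyy[hi] - Pyy[lo]
      sxy <- Pxy[hi] - Pxy[lo]
      r <- (m * sxy - sx * sy) / sqrt((m * sxx - sx^2) * (m * syy - sy^2))
      ok <- ok & is.finite(r) & abs(r) >= r_limit
    }
    if (!any(ok)) next
    n_w <- i1 - i0 + 1L
    wrss <- pmax(swyy - icpt * swy - slope * swxy, 0)
    chi2r <- wrss / pmax(n_w - 2L, 1L)
    cand <- which(ok)
    adequate <- cand[chi2r[cand] <= chi2_adequate]
    if (length(adequate)) {
      pick <- adequate[order(-n_w[adequate], i0[adequate])[1]]
      g <- list(i0 = i0[pick], i1 = i1, len = n_w[pick])
      if (is.null(best) || g$len > best$len ||
          (g$len == best$len && profile$q[g$i0] < profile$q[best$i0]))
        best <- g
    }
    pickf <- cand[which.min(chi2r[cand])]
    gf <- list(i0 = i0[pickf], i1 = i1, chi2 = chi2r[pickf])
    if (is.null(best_fb) || gf$chi2 < best_fb$chi2) best_fb <- gf
  }
  if (is.null(best)) best <- best_fb
  if (!is.null(best))
    best <- guinier_fit(profile, best$i0, best$i1,
                        qmax_rg_limit = qmax_rg_limit)
  if (is.null(best)) {
    out <- list(Rg = NA_real_, Rg_err = NA_real_, I0 = NA_real_,
                I0_err = NA_real_, window = c(NA_integer_, NA_integer_),
                q_range = c(NA_real_, NA_real_), n_points = 0L,
                qmin_Rg = NA_real_, qmax_Rg = NA_real_,
                pearson_r = NA_real_, valid = FALSE,
                reason = paste("no admissible Guinier window found",
                               "(data may be truncated at low q, aggregated",
                               "or affected by interparticle interference)"))
    class(out) <- "guinier_fit"
    return(out)
  }
  best
}
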