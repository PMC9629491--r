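#' Porod invariant and Porod volume
#'
#' Computes the Porod invariant \code{Q = integral_0^q_cut q^2 I(q) dq}
#' (trapezoidal rule) and the Porod volume \code{Vp = 2 pi^2 I(0) / Q}. The
#' unmeasured region \code{[0, q_min)} is filled with the Guinier
#' extrapolation \code{I(0) exp(-q^2 Rg^2 / 3)}; the share of Q coming from
#' that extrapolation is reported. For hydrated globular proteins the ratio
#' \code{Vp / m} is expected around 1.2--1.7 A^3/Da.
#'
#' @param profile a \code{\link{sas_profile}} extending beyond
#'   \code{q Rg ~ 4}.
#' @param guinier a valid \code{\link{guinier_fit}} supplying Rg and I(0).
#' @param q_cut integration cutoff (1/Angstrom) or \code{"auto"} for
#'   \code{min(8 / Rg, q_max)}.
#' @param mass optional molecular mass (Da) for the \code{Vp_over_m} ratio.
#' @param subtract_constant fit \code{I ~ c + K q^-4} over the last decade of
#'   q and subtract \code{c} (if positive) before integrating (default FALSE;
#'   consensus building already fits offsets).
#' @return Object of class \code{"porod_result"}: \code{Q_invariant},
#'   \code{Vp}, \code{q_cut}, \code{Vp_over_m} (or NA),
#'   \code{extrapolated_fraction}, \code{constant_subtracted}.
#' @export
porod_volume <- function(profile, guinier, q_cut = "auto", mass = NULL,
                         subtract_constant = FALSE) {
  stopifnot(inherits(profile, "sas_profile"), inherits(guinier, "guinier_fit"))
  if (!is.finite(guinier$Rg) || guinier$Rg <= 0)
    stop("porod_volume needs a valid Guinier fit")
  Rg <- guinier$Rg; I0 <- guinier$I0
  q <- profile$q; I <- profile$I
  if (max(q) * Rg < 4)
    stop("data too short for the Porod invariant: q_max * Rg = ",
         signif(max(q) * Rg, 3), " < 4")
  if (identical(q_cut, "auto")) q_cut <- min(8 / Rg, max(q))
  if (q_cut <= min(q) || q_cut > max(q) + 1e-12)
    stop("q_cut outside the data range")
  cst <- 0
  if (subtract_constant) {
    sel <- q >= max(min(q), q_cut / 10) & q <= q_cut  # last decade up to q_cut
    X <- cbind(1, q[sel]^-4)
    cf <- stats::lm.fit(X, I[sel])$coefficients
    if (is.finite(cf[1]) && cf[1] > 0) cst <- cf[1]
  }
  keep <- q <= q_cut
  qq <- q[keep]; II <- I[keep] - cst
  # Guinier fill-in below q_min
  qext <- seq(0, qq[1], length.out = 50L)
  Iext <- I0 * exp(-qext^2 * Rg^2 / 3)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  Qext <- trapz(qext, qext^2 * Iext)
  Qdata <- trapz(qq, qq^2 * II)
  Q <- Qext + Qdata
  if (Q <= 0) stop("negative Porod invariant: background pathology")
  Vp <- 2 * pi^2 * I0 / Q
  structure(list(Q_invariant = Q, Vp = Vp, q_cut = q_cut,
                 Vp_over_m = if (is.null(mass)) NA_real_ else Vp / mass,
                 extrapolated_fraction = Qext / Q,
                 constant_subtracted = cst),
            class = "porod_result")
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf("Porod invariant Q = %.5g (q_cut = %.4g 1/A, %.1f%% from Guinier extrapolation)\n",
              x$Q_invariant, x$q_cut, 100 * x$extrapolated_fraction))
  cat(sprintf("  Porod volume Vp = %.0f A^3", x$Vp))
  if (is.finite(x$Vp_over_m)) cat(sprintf("; Vp/m = %.3f A^3/Da", x$Vp_over_m))
  cat("\n")
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Computes \code{y = (q Rg)^2 I(q) / I(0)} against \code{x = q Rg}. For
#' compact globular particles the curve is bell-shaped with a maximum of
#' about 1.1 at \code{q Rg ~ 1.73} (the ideal Guinier-law curve peaks at
#' exactly \code{(sqrt(3), 3/e)}). The peak is located as the first local
#' maximum with \code{x <= 3} and refined on a parabola through the three
#' surrounding samples.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param guinier a valid \code{\link{guinier_fit}} (or any list with
#'   elements \code{Rg} and \code{I0}).
#' @return Object of class \code{"kratky_curve"}: \code{x}, \code{y},
#'   \code{peak_x}, \code{peak_y}.
#' @export
kratky_dimensionless <- function(profile, guinier) {
  stopifnot(inherits(profile, "sas_profile"))
  Rg <- guinier$Rg; I0 <- guinier$I0
  if (!is.finite(Rg) || Rg <= 0 || !is.finite(I0) || I0 <= 0)
    stop("kratky_dimensionless needs a valid Guinier fit (Rg, I0)")
  x <- profile$q * Rg
  y <- x^2 * profile$I / I0
  sel <- which(x > 0 & x <= 3)
  peak_x <- peak_y <- NA_real_
  if (length(sel) >= 3) {
    ii <- sel[-c(1, length(sel))]
    loc <- ii[y[ii] > y[ii - 1] & y[ii] >= y[ii + 1]]
    if (length(loc)) {
      i <- loc[1]   # first local maximum
      # parabolic sub-grid refinement through (x_{i-1..i+1}, y_{i-1..i+1})
      d1 <- (y[i + 1] - y[i - 1]) / 2
      d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
      if (d2 < 0) {
        h <- (x[i + 1] - x[i - 1]) / 2
        peak_x <- x[i] - d1 / d2 * h
        peak_y <- y[i] - d1^2 / (2 * d2)   # parabola vertex ordinate
      } else {
        peak_x <- x[i]; peak_y <- y[i]
      }
    }
  }
  structure(list(x = x, y = y, peak_x = peak_x, peak_y = peak_y),
            class = "kratky_curve")
}

#' @export
print.kratky_curve <- function(x, ...) {
  cat(sprintf("Dimensionless Kratky curve: %d points", length(x$x)))
  if (is.finite(x$peak_x))
    cat(sprintf("; peak (qRg = %.3f, value = %.4f)", x$peak_x, x$peak_y))
  cat("\n")
  invisible(x)
}

#' @export
plot.kratky_curve <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", xlab = expression(q * R[g]),
                 ylab = expression((q * R[g])^2 * I(q) / I(0)), ...)
  graphics::abline(v = sqrt(3), h = 3 / exp(1), lty = 3, col = "grey50")
  if (is.finite(x$peak_x))
    graphics::points(x$peak_x, x$peak_y, pch = 19, col = "red3")
  invisible(x)
}
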