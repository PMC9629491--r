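# Profile-vs-profile comparison: reduced chi-square on pooled errors,
# error-weighted residuals, and the correlation-map (CorMAP) test based on
# the exact distribution of the longest run of same-sign differences under
# a fair coin.

# common-grid check used by all comparison operations
check_common_grid <- function(a, b) {
  if (length(a$q) != length(b$q) ||
      any(abs(a$q - b$q) > 1e-9 * pmax(a$q, b$q)))
    stop("grid mismatch between profiles: rebin onto a common grid first")
}

#' Reduced chi-square between two profiles
#'
#' \code{chi2_red = sum[(I_a - I_b)^2 / (sigma_a^2 + sigma_b^2)] /
#' (n - n_fitted)}. Variances are pooled with no covariance term (independent
#' measurements). For a model curve with no errors, pass it as \code{b} with
#' \code{sigma_b = 0} via \code{model = TRUE}.
#'
#' @param a a \code{\link{sas_profile}}.
#' @param b a \code{\link{sas_profile}} on the same grid, or (with
#'   \code{model = TRUE}) a numeric vector of model intensities.
#' @param n_fitted number of parameters fitted in producing \code{b}
#'   (default 0).
#' @param model treat \code{b} as an error-free model curve.
#' @return List with \code{chi2_reduced}, \code{residuals} (error-weighted),
#'   \code{n}, \code{dof}.
#' @export
chi2_compare <- function(a, b, n_fitted = 0L, model = FALSE) {
  stopifnot(inherits(a, "sas_profile"))
  if (model) {
    Ib <- as.numeric(b)
    stopifnot(length(Ib) == length(a$q))
    pooled <- a$sigma
  } else {
    stopifnot(inherits(b, "sas_profile"))
    check_common_grid(a, b)
    Ib <- b$I
    pooled <- sqrt(a$sigma^2 + b$sigma^2)
  }
  if (any(pooled <= 0)) stop("pooled sigma must be positive")
  res <- (a$I - Ib) / pooled
  n <- length(res)
  dof <- max(n - n_fitted, 1L)
  list(chi2_reduced = sum(res^2) / dof, residuals = res, n = n, dof = dof)
}

#' Error-weighted residuals between two profiles
#'
#' Residuals \code{(I_a - I_b) / pooled sigma} with a flag for the fraction
#' outside +/-3 (which should be about 0.3 percent for well-estimated
#' counting-statistics errors and an unbiased model).
#'
#' @inheritParams chi2_compare
#' @return List with \code{residuals}, \code{frac_outside_3sigma},
#'   \code{systematic} (TRUE when more than half the points share a sign and
#'   exceed 2 in magnitude on average).
#' @export
residual_plot_data <- function(a, b, model = FALSE) {
  cc <- chi2_compare(a, b, model = model)
  res <- cc$residuals
  list(residuals = res,
       frac_outside_3sigma = mean(abs(res) > 3),
       systematic = abs(mean(sign(res))) > 0.9 && mean(abs(res)) > 1.5)
}

#' Length of the longest run of equal signs
#'
#' Sign differences are taken as \code{sign(x)}; zeros inherit the sign of
#' the preceding point (leading zeros count as positive).
#'
#' @param x numeric vector of differences.
#' @return Integer longest-run length.
#' @export
longest_sign_run <- function(x) {
  s <- sign(x)
  if (length(s) == 0L) return(0L)
  if (s[1] == 0) s[1] <- 1
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  max(rle(s)$lengths)
}

#' Exact fair-coin longest-run tail probability
#'
#' Probability that the longest run of identical outcomes in \code{n} fair
#' coin flips is at least \code{C}. Computed from the run-length recursion:
#' the number of binary sequences whose runs are all of length at most
#' \code{c} equals twice the number of compositions of \code{n} into parts of
#' size at most \code{c} (first symbol free, run lengths determine the rest),
#' with the composition count \code{A(n) = sum_{i=1..min(n,c)} A(n-i)},
#' \code{A(0) = 1}. Then \code{P = 1 - 2 A(n) / 2^n} for \code{c = C - 1}.
#'
#' @param n number of points (flips).
#' @param C observed longest-run length (1..n).
#' @return Probability in [0, 1].
#' @export
cormap_pvalue <- function(n, C) {
  stopifnot(n >= 1L, C >= 1L)
  if (C > n) return(0)
  if (C == 1L) return(1)
  cmax <- C - 1L
  # a(m) = A(m) / 2^m with A(m) the number of compositions of m into parts
  # <= cmax; normalising inside the recursion keeps it finite for any n
  a <- numeric(n + 1L)
  a[1] <- 1
  for (m in seq_len(n)) {
    i <- seq_len(min(m, cmax))
    a[m + 1L] <- sum(a[m - i + 1L] * 2^-i)
  }
  p_ok <- 2 * a[n + 1L]
  max(0, min(1, 1 - p_ok))
}

#' Correlation-map (longest-run) test between two profiles
#'
#' The CorMAP-style test statistic is the longest run C of same-sign
#' differences \code{I_a - I_b} along q. Under the null hypothesis that the
#' two profiles measure the same curve with independent symmetric noise, the
#' signs are fair coin flips, and the exact tail probability
#' \code{P = Pr(longest run >= C)} follows from \code{\link{cormap_pvalue}}.
#' The adjusted value applies a Bonferroni factor for the number of pairwise
#' comparisons performed in a session.
#'
#' @param a,b \code{\link{sas_profile}} objects on a common grid with at
#'   least 5 points.
#' @param n_comparisons Bonferroni factor (default 1).
#' @return List with \code{cormap_C}, \code{cormap_P},
#'   \code{cormap_P_adjusted}, \code{n}.
#' @export
cormap_test <- function(a, b, n_comparisons = 1L) {
  stopifnot(inherits(a, "sas_profile"), inherits(b, "sas_profile"))
  check_common_grid(a, b)
  n <- length(a$q)
  if (n < 5L) stop("CorMAP test needs at least 5 common points")
  C <- longest_sign_run(a$I - b$I)
  P <- cormap_pvalue(n, C)
  list(cormap_C = C, cormap_P = P,
       cormap_P_adjusted = min(1, n_comparisons * P), n = n)
}

#' Full profile comparison
#'
#' Combines \code{\link{chi2_compare}}, \code{\link{cormap_test}} and
#' \code{\link{residual_plot_data}} in one classed result.
#'
#' @inheritParams cormap_test
#' @param n_fitted parameters fitted in producing \code{b}.
#' @return Object of class \code{"sas_comparison"}.
#' @export
compare_profiles <- function(a, b, n_fitted = 0L, n_comparisons = 1L) {
  cc <- chi2_compare(a, b, n_fitted = n_fitted)
  cm <- cormap_test(a, b, n_comparisons = n_comparisons)
  rp <- residual_plot_data(a, b)
  structure(c(cc[c("chi2_reduced", "n", "dof")], cm[-4],
              rp[c("frac_outside_3sigma", "systematic")],
              list(residuals = cc$residuals)),
            class = "sas_comparison")
}

#' @export
print.sas_comparison <- function(x, ...) {
  cat(sprintf("Profile comparison over %d points (dof %d)\n", x$n, x$dof))
  cat(sprintf("  reduced chi^2 = %.4g\n", x$chi2_reduced))
  cat(sprintf("  CorMAP: longest run C = %d, P = %.4g (adjusted %.4g)\n",
              x$cormap_C, x$cormap_P, x$cormap_P_adjusted))
  cat(sprintf("  fraction of residuals outside +/-3: %.3g%%%s\n",
              100 * x$frac_outside_3sigma,
              if (isTRUE(x$systematic)) "  [systematic deviation]" else ""))
  invisible(x)
}
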