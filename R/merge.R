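# Splicing of low-q data (SEC or dilute batch) with high-q data (concentrated
# batch): a multiplicative scale is found in a mid-q overlap region, the
# spliced curve takes the low-q profile below a cut and the scaled high-q
# profile above it, and an iterative q_min scan guards against low-q
# contamination (aggregate or interparticle interference) from the
# concentrated data.

#' Multiplicative scale between two profiles over an overlap window
#'
#' Finds the factor c minimising
#' \code{sum (I_low - c I_high)^2 / (sigma_low^2 + c^2 sigma_high^2)} over
#' points of the window present in both profiles (matched by nearest q within
#' half a grid step). No offset is fitted: residual background offsets are the
#' job of consensus combination. The weights follow c, so the closed-form
#' weighted-ratio update is iterated to convergence (1e-10).
#'
#' @param low,high \code{\link{sas_profile}} objects.
#' @param window numeric \code{c(q_lo, q_hi)} overlap window; both profiles
#'   need at least \code{min_points} points inside.
#' @param min_points minimum shared points required (default 20).
#' @return List with \code{c} (scale applied to \code{high}), \code{c_err},
#'   \code{n}, \code{window}.
#' @export
scale_overlap <- function(low, high, window, min_points = 20L) {
  stopifnot(inherits(low, "sas_profile"), inherits(high, "sas_profile"),
            length(window) == 2L, window[1] < window[2])
  li <- which(low$q >= window[1] & low$q <= window[2])
  hi <- which(high$q >= window[1] & high$q <= window[2])
  if (length(li) < min_points || length(hi) < min_points)
    stop(sprintf("insufficient overlap in window [%g, %g]: %d low / %d high points (need %d each)",
                 window[1], window[2], length(li), length(hi), min_points))
  # match low points to nearest high point within half the local spacing
  j <- findInterval(low$q[li], high$q[hi]) ; j[j < 1L] <- 1L
  jn <- pmin(j + 1L, length(hi))
  nearer <- abs(high$q[hi][jn] - low$q[li]) < abs(high$q[hi][j] - low$q[li])
  j[nearer] <- jn[nearer]
  tolq <- stats::median(diff(low$q[li])) / 2
  okm <- abs(high$q[hi][j] - low$q[li]) <= tolq
  if (sum(okm) < min_points)
    stop(sprintf("insufficient matched overlap points in window [%g, %g]",
                 window[1], window[2]))
  yl <- low$I[li][okm]; sl <- low$sigma[li][okm]
  yh <- high$I[hi][j][okm]; sh <- high$sigma[hi][j][okm]
  cc <- stats::median(yl / yh)
  if (!is.finite(cc) || cc <= 0) cc <- sum(yl * yh) / sum(yh^2)
  for (it in 1:200) {
    w <- 1 / (sl^2 + cc^2 * sh^2)
    cn <- sum(w * yl * yh) / sum(w * yh^2)
    if (abs(cn - cc) <= 1e-10 * abs(cc)) { cc <- cn; break }
    cc <- cn
  }
  w <- 1 / (sl^2 + cc^2 * sh^2)
  list(c = cc, c_err = 1 / sqrt(sum(w * yh^2)), n = sum(okm),
       window = window)
}

# default overlap window: ~n_points points centred at the geometric mean of
# the two profiles' q ranges, clipped to the shared range
default_overlap_window <- function(low, high, n_points = 75L) {
  qlo <- max(min(low$q), min(high$q))
  qhi <- min(max(low$q), max(high$q))
  if (qhi <= qlo) stop("profiles have no overlapping q-range")
  centre <- sqrt(max(qlo, 1e-6) * qhi)
  centre <- min(max(centre, qlo), qhi)
  dq <- stats::median(diff(low$q[low$q >= qlo & low$q <= qhi]))
  half <- n_points / 2 * dq
  c(max(qlo, centre - half), min(qhi, centre + half))
}

#' Merge (splice) a low-q and a high-q profile
#'
#' After scaling the high-q profile onto the low-q profile in the overlap
#' window (\code{\link{scale_overlap}}), the merged curve takes the low-q
#' profile's points for \code{q < cut_q} and the scaled high-q points for
#' \code{q >= cut_q}; the high-q errors are scaled by the same factor. With
#' \code{cut_q = "auto"} the cut is placed inside the overlap window at the
#' first q where the scaled high-q error drops below the low-q error (so the
#' overlap keeps only the lower-uncertainty side of each region), falling
#' back to the window centre. Every output point is an input point times its
#' block's scale: no interpolation. Provenance (source of each point) is
#' recorded. Additional high-q profiles may be supplied for three-way merges.
#'
#' @param low low-q \code{\link{sas_profile}}.
#' @param high high-q \code{\link{sas_profile}} (or list of profiles ordered
#'   low to high for a multi-way merge).
#' @param cut_q splice q value(s), or \code{"auto"}.
#' @param window overlap window passed to \code{\link{scale_overlap}}, or
#'   \code{"auto"} (default: about 75 points centred at the geometric mean of
#'   the shared q-range).
#' @param qmin_high drop high-q points below this q before merging (the
#'   contamination control knob of \code{\link{merge_scan}}).
#' @return A \code{\link{sas_profile}} with \code{meta$provenance} (integer
#'   source index per point: 1 = low, 2... = high profiles in order),
#'   \code{meta$scales} and \code{meta$cut_q}.
#' @export
merge_profiles <- function(low, high, cut_q = "auto", window = "auto",
                           qmin_high = NULL) {
  highs <- if (inherits(high, "sas_profile")) list(high) else high
  stopifnot(length(highs) >= 1L)
  if (!is.null(qmin_high))
    highs <- lapply(highs, function(h) profile_subset(h, h$q >= qmin_high))
  out <- low
  prov <- rep(1L, length(low$q))
  scales <- numeric(0)
  cuts <- numeric(0)
  for (s in seq_along(highs)) {
    h <- highs[[s]]
    win <- if (identical(window, "auto")) default_overlap_window(out, h)
           else window
    sc <- scale_overlap(out, h, win)
    cq <- cut_q
    if (identical(cq, "auto")) {
      # the low-q side of the splice always comes from the low-q (SEC/dilute)
      # profile -- that is the point of the merge -- so the automatic cut is
      # restricted to the upper half of the overlap window, placed at the
      # first q there where the scaled high-q error drops below the low-q
      # error (eliminating unnecessary high-uncertainty overlap points),
      # defaulting to the window centre
      cq <- mean(win)
      hi_in <- which(h$q >= cq & h$q <= win[2])
      lo_in <- which(out$q >= win[1] & out$q <= win[2])
      if (length(hi_in) && length(lo_in)) {
        slo <- stats::approx(out$q[lo_in], out$sigma[lo_in], xout = h$q[hi_in],
                             rule = 2)$y
        better <- which(sc$c * h$sigma[hi_in] < slo)
        if (length(better)) cq <- h$q[hi_in[better[1]]]
      }
    } else if (length(cut_q) >= s) cq <- cut_q[s]
    keep_lo <- out$q < cq
    keep_hi <- h$q >= cq
    if (!any(keep_lo) || !any(keep_hi))
      stop("merge plan error: cut at q = ", cq,
           " leaves one side of the splice empty")
    newq <- c(out$q[keep_lo], h$q[keep_hi])
    if (any(diff(newq) <= 0))
      stop("merge plan error: output q not strictly increasing at the cut")
    prov <- c(prov[keep_lo], rep(s + 1L, sum(keep_hi)))
    out <- sas_profile(newq,
                       c(out$I[keep_lo], sc$c * h$I[keep_hi]),
                       c(out$sigma[keep_lo], sc$c * h$sigma[keep_hi]),
                       meta = low$meta)
    scales <- c(scales, sc$c)
    cuts <- c(cuts, cq)
  }
  if (length(cuts) > 1 && any(diff(cuts) <= 0))
    stop("merge plan error: cut q values must be strictly increasing")
  out$meta$provenance <- prov
  out$meta$scales <- scales
  out$meta$cut_q <- cuts
  out
}

#' Contamination scan for a merge
#'
#' Systematically raises the minimum q accepted from the high-concentration
#' data -- each candidate q_min is used as the splice cut, so the merged curve
#' is the low-q (SEC/dilute) profile below q_min and the scaled batch profile
#' above it -- recomputes the Guinier fit and P(r) of each merge, and compares
#' against the low-q-only reference. The recommended q_min is the smallest
#' candidate at which the merged Rg agrees with the reference within one
#' combined standard error and d_max within \code{dmax_tol} Angstrom -- i.e.
#' the point at which the concentrated data stop altering the derived
#' structural parameters. Candidates should start around the beginning of the
#' mid-q overlap region (above the Guinier range of the reference, so that the
#' low-q information of every merge is shared with the reference).
#'
#' @param low low-q reference \code{\link{sas_profile}} (assumed clean).
#' @param high high-q \code{\link{sas_profile}} under suspicion.
#' @param qmin_candidates increasing q_min values to test.
#' @param d_range d_max bracket for \code{\link{refine_dmax}} on the
#'   reference; the same refined d_max is used for all candidates' P(r).
#' @param dmax_tol d_max agreement tolerance in Angstrom (default 3, the
#'   noise band of the d_max estimator at percent-level noise).
#' @param ... passed to \code{\link{merge_profiles}}.
#' @return List of class \code{"sas_mergescan"}: \code{table} (one row per
#'   candidate: qmin, Rg, Rg_err, dRg_sigma, d_max, accepted),
#'   \code{recommended_qmin} (NA if no candidate is stable),
#'   \code{reference} (Rg/d_max of the low-q-only data).
#' @export
merge_scan <- function(low, high, qmin_candidates, d_range = NULL,
                       dmax_tol = 3, ...) {
  stopifnot(is.numeric(qmin_candidates), !is.unsorted(qmin_candidates))
  g_ref <- auto_guinier(low)
  if (!isTRUE(g_ref$valid)) stop("reference profile has no valid Guinier fit")
  if (is.null(d_range)) d_range <- c(1.5 * g_ref$Rg, 4.5 * g_ref$Rg)
  d_ref <- as.integer(refine_dmax(low, d_range))
  pr_ref <- pr_transform(low, d_ref)
  rows <- lapply(qmin_candidates, function(qm) {
    m <- tryCatch(merge_profiles(low, high, cut_q = qm, qmin_high = qm, ...),
                  error = function(e) NULL)
    if (is.null(m)) return(data.frame(qmin = qm, Rg = NA, Rg_err = NA,
                                      dRg_sigma = NA, d_max = NA,
                                      chi2_pr = NA, accepted = FALSE))
    g <- auto_guinier(m)
    dm <- tryCatch(as.integer(refine_dmax(m, d_range)),
                   error = function(e) NA_integer_)
    pr <- tryCatch(pr_transform(m, if (is.na(dm)) d_ref else dm),
                   error = function(e) NULL)
    dsig <- abs(g$Rg - g_ref$Rg) / sqrt(g$Rg_err^2 + g_ref$Rg_err^2)
    acc <- isTRUE(g$valid) && is.finite(dsig) && dsig < 1 &&
      !is.na(dm) && abs(dm - d_ref) <= dmax_tol
    data.frame(qmin = qm, Rg = g$Rg, Rg_err = g$Rg_err, dRg_sigma = dsig,
               d_max = dm, chi2_pr = if (is.null(pr)) NA else pr$chi2_reduced,
               accepted = acc)
  })
  tab <- do.call(rbind, rows)
  rec <- if (any(tab$accepted)) tab$qmin[which(tab$accepted)[1]] else NA_real_
  structure(list(table = tab, recommended_qmin = rec,
                 reference = list(Rg = g_ref$Rg, Rg_err = g_ref$Rg_err,
                                  d_max = d_ref)),
            class = "sas_mergescan")
}

#' @export
print.sas_mergescan <- function(x, ...) {
  cat(sprintf("Merge q_min scan (reference Rg = %.3f +/- %.3f A, d_max = %d A)\n",
              x$reference$Rg, x$reference$Rg_err, x$reference$d_max))
  print(x$table, row.names = FALSE)
  if (is.na(x$recommended_qmin))
    cat("no candidate q_min reached the stability criterion\n")
  else
    cat(sprintf("recommended q_min for the high-concentration data: %g 1/A\n",
                x$recommended_qmin))
  invisible(x)
}
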