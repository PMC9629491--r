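# Consensus combination of independently measured scattering profiles:
# per-dataset scale factors a_j and additive offsets b_j are found by
# Levenberg-Marquardt minimisation of all pairwise error-weighted
# discrepancies on a common q-grid, with optional modified Z-score outlier
# rejection (iterated to convergence) and a greedy high-error filter.

# Robust affine alignment y ~ a x + b: Theil-Sen slope over pairwise
# differences (exact on affine data, ~29% outlier breakdown, safe for
# intensities that dip negative) and median-residual offset.
robust_affine <- function(x, y) {
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  a <- stats::median(dy[keep] / dx[keep])
  if (!is.finite(a) || a <= 0) a <- 1
  c(a = a, b = stats::median(y - a * x))
}

# Internal: rebin a list of profiles onto one grid and align as matrices.
# Returns N x nb matrices I, S and logical 'present', plus grid centers.
align_profiles <- function(profiles, grid) {
  stopifnot(length(profiles) >= 2L, inherits(grid, "sas_qgrid"))
  nb <- length(grid$centers)
  N <- length(profiles)
  I <- matrix(NA_real_, N, nb)
  S <- matrix(NA_real_, N, nb)
  for (j in seq_len(N)) {
    r <- rebin(profiles[[j]], grid)
    idx <- r$meta$bin_index
    I[j, idx] <- r$I
    S[j, idx] <- r$sigma
  }
  list(I = I, S = S, present = !is.na(I), q = grid$centers)
}

#' Fit per-dataset scale factors and background offsets
#'
#' Determines one multiplicative scale \code{a_j} and one additive offset
#' \code{b_j} per dataset by minimising the sum over all dataset pairs
#' \code{j < k} and shared grid points \code{i} of
#' \deqn{[(a_j I_j(q_i) + b_j) - (a_k I_k(q_i) + b_k)]^2 /
#'       (a_j^2 \sigma_j^2(q_i) + a_k^2 \sigma_k^2(q_i))}
#' by Levenberg-Marquardt iteration (weights follow the current scales, i.e.
#' iteratively reweighted). The gauge is fixed by \code{a = 1, b = 0} for the
#' reference dataset, so the consensus is on the reference's (arbitrary)
#' intensity scale.
#'
#' @param profiles list of \code{\link{sas_profile}} objects. If \code{grid}
#'   is supplied they are re-gridded onto it; otherwise they must already share
#'   an identical q vector.
#' @param grid optional \code{\link{qgrid}}.
#' @param mask optional logical matrix (dataset x grid point) of points allowed
#'   to contribute; defaults to all present points.
#' @param reference index of the gauge dataset; default is the dataset
#'   covering the most grid points.
#' @param max_iter maximum Levenberg-Marquardt iterations (default 200).
#' @return An object of class \code{"sas_scaling"}: list with \code{a},
#'   \code{b}, \code{se_a}, \code{se_b}, \code{reference},
#'   \code{objective_f}, \code{n_lm_iterations}, \code{converged}.
#' @export
fit_scales <- function(profiles, grid = NULL, mask = NULL, reference = NULL,
                       max_iter = 200) {
  al <- if (!is.null(grid)) align_profiles(profiles, grid) else {
    q0 <- profiles[[1]]$q
    for (p in profiles[-1])
      if (length(p$q) != length(q0) || any(abs(p$q - q0) > 1e-9 * q0))
        stop("profiles are not on a common grid; supply 'grid' to rebin")
    list(I = do.call(rbind, lapply(profiles, `[[`, "I")),
         S = do.call(rbind, lapply(profiles, `[[`, "sigma")),
         present = matrix(TRUE, length(profiles), length(q0)), q = q0)
  }
  fit_scales_matrix(al$I, al$S,
                    mask = if (is.null(mask)) al$present else mask & al$present,
                    reference = reference, max_iter = max_iter)
}

# Matrix-level engine behind fit_scales(); I, S are N x nb with NA for absent
# points, mask a logical N x nb matrix.
fit_scales_matrix <- function(I, S, mask, reference = NULL, max_iter = 200) {
  N <- nrow(I)
  if (N < 2L) stop("need at least 2 datasets")
  if (is.null(reference)) reference <- which.max(rowSums(mask))
  pairs <- utils::combn(N, 2)
  shared <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    j <- pairs[1, p]; k <- pairs[2, p]
    sh <- which(mask[j, ] & mask[k, ])
    shared[[p]] <- if (length(sh) >= 5L) sh else integer(0)
  }
  # connectivity of the overlap graph through shared points
  adj <- matrix(FALSE, N, N)
  for (p in seq_len(ncol(pairs)))
    if (length(shared[[p]]))
      adj[pairs[1, p], pairs[2, p]] <- adj[pairs[2, p], pairs[1, p]] <- TRUE
  seen <- logical(N); seen[reference] <- TRUE
  repeat {
    new <- which(!seen & apply(adj[, seen, drop = FALSE], 1, any))
    if (!length(new)) break
    seen[new] <- TRUE
  }
  if (!all(seen))
    stop("dataset(s) ", paste(which(!seen), collapse = ", "),
         " share too few grid points with the rest (disconnected overlap graph)")

  free <- setdiff(seq_len(N), reference)
  unpack <- function(par) {
    a <- rep(1, N); b <- rep(0, N)
    a[free] <- exp(par[seq_along(free)])
    b[free] <- par[length(free) + seq_along(free)]
    list(a = a, b = b)
  }
  residfn <- function(par) {
    th <- unpack(par)
    out <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      sh <- shared[[p]]
      if (!length(sh)) { out[[p]] <- numeric(0); next }
      j <- pairs[1, p]; k <- pairs[2, p]
      num <- (th$a[j] * I[j, sh] + th$b[j]) - (th$a[k] * I[k, sh] + th$b[k])
      den <- sqrt(th$a[j]^2 * S[j, sh]^2 + th$a[k]^2 * S[k, sh]^2)
      out[[p]] <- num / den
    }
    unlist(out)
  }
  # start from a robust affine alignment to the reference over shared points
  start_a <- rep(1, N); start_b <- rep(0, N)
  for (j in free) {
    sh <- which(mask[j, ] & mask[reference, ])
    if (length(sh) >= 5L) {
      ab <- robust_affine(I[j, sh], I[reference, sh])
      start_a[j] <- ab[["a"]]; start_b[j] <- ab[["b"]]
    }
  }
  par0 <- c(log(start_a[free]), start_b[free])
  fit <- minpack.lm::nls.lm(par0, fn = residfn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, ptol = 1e-10, gtol = 0,
                              maxiter = max_iter))
  th <- unpack(fit$par)
  converged <- fit$info %in% c(1L, 2L, 3L, 4L)
  if (!converged)
    warning("scale/offset fit did not converge: ", fit$message)
  # standard errors from the LM covariance (J'J)^-1; residuals are already
  # error-weighted so no deviance scaling is applied
  se_a <- rep(NA_real_, N); se_b <- rep(NA_real_, N)
  cv <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cv)) {
    sds <- sqrt(pmax(diag(cv), 0))
    se_a[free] <- th$a[free] * sds[seq_along(free)]   # delta method on log a
    se_b[free] <- sds[length(free) + seq_along(free)]
    se_a[reference] <- 0; se_b[reference] <- 0
  }
  structure(list(a = th$a, b = th$b, se_a = se_a, se_b = se_b,
                 reference = reference,
                 objective_f = sum(residfn(fit$par)^2),
                 n_lm_iterations = fit$niter, converged = converged),
            class = "sas_scaling")
}

#' @export
print.sas_scaling <- function(x, ...) {
  cat(sprintf("Pairwise scale/offset solution (%d datasets, reference %d)\n",
              length(x$a), x$reference))
  cat(sprintf("  objective f = %.6g after %d LM iterations (%s)\n",
              x$objective_f, x$n_lm_iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(a = x$a, b = x$b, se_a = x$se_a, se_b = x$se_b))
  invisible(x)
}

#' @export
coef.sas_scaling <- function(object, ...) {
  cbind(a = object$a, b = object$b)
}

#' High-error inclusion filter for one grid point
#'
#' Sorts the contributing values at one q by the magnitude of their errors and
#' keeps the ascending-error prefix that minimises the propagated error of the
#' plain average, \code{g(m) = sqrt(sum sigma_{1..m}^2) / m}: data with errors
#' of increasing magnitude are added only for as long as they do not increase
#' the propagated average error. The calculation depends only on the errors,
#' never on the intensities. The smallest-error point is always included;
#' ties keep input order. By construction the filtered propagated error never
#' exceeds the all-points plain-average error (\code{g(m*) <= g(n)}).
#'
#' @param sigmas positive numeric vector of (scaled) standard errors at one
#'   grid point.
#' @param values ignored (kept for a uniform filter signature).
#' @return Logical inclusion mask, same length and order as \code{sigmas}.
#' @export
error_filter <- function(sigmas, values = NULL) {
  n <- length(sigmas)
  if (n == 0L) return(logical(0))
  stopifnot(all(sigmas > 0))
  o <- order(sigmas)              # stable: ties broken by original index
  g <- sqrt(cumsum(sigmas[o]^2)) / seq_len(n)
  m_star <- which.min(g)
  inc <- logical(n)
  inc[o[seq_len(m_star)]] <- TRUE
  inc
}

#' Modified Z-score outlier test for one grid point
#'
#' Flags intensity values unlikely to come from the expected distribution at
#' one q using the modified Z-score of Iglewicz & Hoaglin:
#' \code{Z_j = 0.6745 |x_j - MED| / MAD}, with MED the median and MAD the
#' (unscaled) median absolute deviation of the scaled-and-offset intensities.
#' Values with \code{Z > z_threshold} are removed. With fewer than 3 values,
#' or when MAD is zero, no removal is attempted.
#'
#' @param values numeric vector of scaled intensities at one grid point.
#' @param z_threshold removal threshold on Z (default 2).
#' @return List with \code{z}, logical \code{removed}, \code{med}, \code{mad}
#'   and a \code{degenerate} flag (MAD == 0 or fewer than 3 values).
#' @export
outlier_filter <- function(values, z_threshold = 2) {
  n <- length(values)
  if (n < 3L)
    return(list(z = rep(0, n), removed = rep(FALSE, n),
                med = stats::median(values), mad = NA_real_, degenerate = TRUE))
  med <- stats::median(values)
  md <- stats::mad(values, center = med, constant = 1)
  # MAD of zero -- including a MAD at floating-point jitter level relative to
  # the values themselves -- disables removal at this point
  if (md <= 1e-12 * max(abs(med), max(abs(values - med))))
    return(list(z = rep(0, n), removed = rep(FALSE, n),
                med = med, mad = md, degenerate = TRUE))
  z <- 0.6745 * abs(values - med) / md
  list(z = z, removed = z > z_threshold, med = med, mad = md,
       degenerate = FALSE)
}

#' Combine independent measurements into a consensus profile
#'
#' Re-grids all profiles onto a common q-scale, fits per-dataset scales and
#' offsets (\code{\link{fit_scales}}), optionally removes outliers by the
#' modified Z-score and refits until no more outliers appear, then optionally
#' applies the greedy high-error filter, and averages: the consensus intensity
#' at each grid point is the plain (unweighted) mean of the included scaled
#' values \code{a_j I_j + b_j}, and the consensus error is
#' \code{sqrt(sum a_j^2 sigma_j^2) / M} over the M included datasets.
#'
#' @param profiles list of at least two \code{\link{sas_profile}} objects.
#' @param grid a \code{\link{qgrid}} (see \code{\link{default_grid}}).
#' @param filter \code{"both"} (default), \code{"outlier"}, \code{"error"} or
#'   \code{"none"}.
#' @param z_threshold modified Z-score removal threshold (default 2).
#' @param qmin optional numeric vector (one per dataset) of low-q limits, e.g.
#'   each dataset's Guinier q_min, applied before combination; NA entries
#'   leave that dataset untruncated.
#' @param reference gauge dataset index (default: widest grid coverage).
#' @param max_outer maximum outlier/refit cycles (default 20).
#' @return An object of class \code{"sas_consensus"}: list with
#'   \code{consensus} (a \code{\link{sas_profile}}), \code{scaling}
#'   (\code{"sas_scaling"}), \code{inclusion} (dataset x grid point logical),
#'   \code{exclusion_reason} (character matrix: "", "absent", "outlier",
#'   "error", "qmin"), \code{outliers} (per-point med/MAD/Z of the final
#'   iteration and a per-iteration removal count), \code{n_outer_iterations},
#'   \code{filter}, \code{f_history} and \code{grid}.
#' @examples
#' q <- seq(0.005, 0.4, by = 0.005)
#' ideal <- sphere_profile(R = 20, I0 = 1, q = q)
#' obs <- lapply(1:4, function(j) simulate_instrument(ideal,
#'   a = j, b = 0.001 * j, noise_k = 0.01, seed = j))
#' cons <- sas_combine(obs, qgrid(c(0, 0.4, 0.005)), reference = 1)
#' print(cons)
#' @export
sas_combine <- function(profiles, grid,
                        filter = c("both", "outlier", "error", "none"),
                        z_threshold = 2, qmin = NULL, reference = NULL,
                        max_outer = 20) {
  filter <- match.arg(filter)
  stopifnot(length(profiles) >= 2L)
  if (!is.null(qmin)) {
    stopifnot(length(qmin) == length(profiles))
    profiles <- lapply(seq_along(profiles), function(j) {
      if (is.na(qmin[j])) return(profiles[[j]])
      profile_subset(profiles[[j]], profiles[[j]]$q >= qmin[j])
    })
  }
  al <- align_profiles(profiles, grid)
  N <- nrow(al$I); nb <- ncol(al$I)
  mask <- al$present
  reason <- matrix("", N, nb)
  reason[!al$present] <- "absent"

  do_outlier <- filter %in% c("both", "outlier")
  do_error <- filter %in% c("both", "error")

  # Outlier loop: fit scales on the currently trusted points, then re-identify
  # the outlier set from scratch under the new scaling. Median and MAD are
  # taken over ALL present values at each q (they are robust to the outliers
  # by construction, and keeping the sample fixed avoids the trimming ratchet
  # of ever-shrinking robust statistics); points flagged under a
  # spike-distorted early fit are re-admitted once the scaling recovers.
  # Converged when the removed set stops changing.
  f_hist <- numeric(0)
  removals_per_iter <- integer(0)
  outer <- 0L
  last_report <- NULL
  removed <- matrix(FALSE, N, nb)
  seen_sets <- character(0)
  if (do_outlier) {
    # robust pre-screen: gross spikes would distort the least-squares scale
    # fit itself, so the first outlier identification aligns each dataset to
    # the reference with a Theil-Sen affine fit on shared intensities (exact
    # on affine data, immune to spikes up to a ~29% breakdown)
    ref0 <- if (is.null(reference)) which.max(rowSums(mask)) else reference
    a_rob <- rep(1, N); b_rob <- rep(0, N)
    for (j in seq_len(N)) {
      if (j == ref0) next
      sh <- which(al$present[j, ] & al$present[ref0, ])
      if (length(sh) >= 5L) {
        ab <- robust_affine(al$I[j, sh], al$I[ref0, sh])
        a_rob[j] <- ab[["a"]]; b_rob[j] <- ab[["b"]]
      }
    }
    X0 <- a_rob * al$I + b_rob
    for (i in seq_len(nb)) {
      pres <- which(al$present[, i])
      if (length(pres) < 3L) next
      rep_i <- outlier_filter(X0[pres, i], z_threshold)
      if (!rep_i$degenerate) removed[pres[rep_i$removed], i] <- TRUE
    }
  }
  repeat {
    outer <- outer + 1L
    mask <- al$present & !removed
    sc <- fit_scales_matrix(al$I, al$S, mask, reference = reference)
    f_hist <- c(f_hist, sc$objective_f)
    if (!do_outlier || outer > max_outer) break
    X <- sc$a * al$I + sc$b          # row-wise recycling: a,b length N
    new_removed <- matrix(FALSE, N, nb)
    med <- mad_ <- rep(NA_real_, nb)
    zmat <- matrix(NA_real_, N, nb)
    for (i in seq_len(nb)) {
      pres <- which(al$present[, i])
      if (length(pres) < 3L) next
      rep_i <- outlier_filter(X[pres, i], z_threshold)
      if (rep_i$degenerate) next
      med[i] <- rep_i$med; mad_[i] <- rep_i$mad
      zmat[pres, i] <- rep_i$z
      new_removed[pres[rep_i$removed], i] <- TRUE
    }
    last_report <- list(med = med, mad = mad_, z = zmat)
    n_changed <- sum(new_removed != removed)
    removals_per_iter <- c(removals_per_iter, sum(new_removed & !removed))
    if (n_changed == 0L) break
    key <- paste(which(new_removed), collapse = ",")
    if (key %in% seen_sets) {
      # the iteration revisits an earlier removal set (limit cycle between
      # near-equivalent solutions): settle on the revisited set
      removed <- new_removed
      mask <- al$present & !removed
      sc <- fit_scales_matrix(al$I, al$S, mask, reference = reference)
      f_hist <- c(f_hist, sc$objective_f)
      break
    }
    seen_sets <- c(seen_sets, paste(which(removed), collapse = ","), key)
    removed <- new_removed
  }
  if (do_outlier && outer > max_outer)
    warning("outlier iteration did not settle within ", max_outer, " cycles")
  mask <- al$present & !removed
  reason[removed] <- "outlier"

  a <- sc$a; b <- sc$b
  X <- a * al$I + b
  SS <- a * al$S
  if (do_error) {
    for (i in seq_len(nb)) {
      inc <- which(mask[, i])
      if (length(inc) < 2L) next
      keep <- error_filter(SS[inc, i])
      drop_j <- inc[!keep]
      if (length(drop_j)) {
        mask[drop_j, i] <- FALSE
        reason[drop_j, i] <- "error"
      }
    }
  }

  M <- colSums(mask)
  occ <- which(M >= 1L)
  if (!length(occ)) stop("no grid point retains any included dataset")
  if (length(occ) < sum(colSums(al$present) > 0))
    warning(sum(colSums(al$present) > 0) - length(occ),
            " grid point(s) lost all contributing datasets and were dropped")
  consI <- vapply(occ, function(i) mean(X[mask[, i], i]), numeric(1))
  consS <- vapply(occ, function(i)
    sqrt(sum(SS[mask[, i], i]^2)) / M[i], numeric(1))
  consensus <- sas_profile(al$q[occ], consI, consS,
                           meta = list(label = "consensus",
                                       n_datasets = N,
                                       n_included = M[occ]))
  structure(list(consensus = consensus, scaling = sc, inclusion = mask,
                 exclusion_reason = reason,
                 outliers = list(report = last_report,
                                 removed_per_iteration = removals_per_iter),
                 n_outer_iterations = outer, filter = filter,
                 z_threshold = z_threshold, f_history = f_hist,
                 grid = grid, q = al$q, scaled_I = X, scaled_S = SS,
                 present = al$present),
            class = "sas_consensus")
}

#' @export
print.sas_consensus <- function(x, ...) {
  cat(sprintf("Consensus of %d datasets on %d grid points (filter: %s)\n",
              nrow(x$inclusion), length(x$consensus$q), x$filter))
  cat(sprintf("  scale/offset fit: f = %.6g, %d outer iteration(s)\n",
              x$scaling$objective_f, x$n_outer_iterations))
  n_out <- sum(x$exclusion_reason == "outlier")
  n_err <- sum(x$exclusion_reason == "error")
  cat(sprintf("  excluded points: %d outlier, %d high-error\n", n_out, n_err))
  invisible(x)
}

#' @export
summary.sas_consensus <- function(object, ...) {
  per_ds <- data.frame(
    a = object$scaling$a, b = object$scaling$b,
    n_present = rowSums(object$present),
    n_included = rowSums(object$inclusion),
    n_outlier = rowSums(object$exclusion_reason == "outlier"),
    n_error = rowSums(object$exclusion_reason == "error"))
  out <- list(datasets = per_ds,
              n_grid = length(object$consensus$q),
              filter = object$filter,
              f_history = object$f_history,
              n_outer_iterations = object$n_outer_iterations)
  class(out) <- "summary.sas_consensus"
  out
}

#' @export
print.summary.sas_consensus <- function(x, ...) {
  cat(sprintf("Consensus summary (filter: %s, %d outer iterations)\n",
              x$filter, x$n_outer_iterations))
  print(x$datasets)
  cat("objective f by iteration:", paste(signif(x$f_history, 6), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
coef.sas_consensus <- function(object, ...) coef(object$scaling)

#' @export
plot.sas_consensus <- function(x, ...) {
  keep <- x$consensus$I > 0
  graphics::plot(x$consensus$q[keep], x$consensus$I[keep], log = "y",
                 type = "n", xlab = "q (1/A)", ylab = "I(q) (arbitrary units)",
                 ...)
  for (j in seq_len(nrow(x$inclusion))) {
    i <- which(x$present[j, ] & x$scaled_I[j, ] > 0)
    graphics::points(x$q[i], x$scaled_I[j, i], col = "grey70", pch = ".",
                     cex = 2)
  }
  graphics::lines(x$consensus$q[keep], x$consensus$I[keep], col = "red3",
                  lwd = 2)
  invisible(x)
}

#' Consensus pipeline with per-dataset Guinier truncation
#'
#' Convenience wrapper applying the standard consensus protocol: run
#' \code{\link{auto_guinier}} on each profile and truncate it below its
#' selected Guinier q_min (limiting parasitic scattering and residual
#' heterogeneity at low q), then combine on the given grid with the requested
#' filters.
#'
#' @param profiles list of \code{\link{sas_profile}} objects.
#' @param grid a \code{\link{qgrid}}.
#' @param filter filter mode passed to \code{\link{sas_combine}}.
#' @param ... further arguments to \code{\link{sas_combine}}.
#' @return A \code{"sas_consensus"} object; per-dataset Guinier fits in
#'   \code{$guinier_fits}.
#' @export
consensus_pipeline <- function(profiles, grid, filter = "both", ...) {
  gfits <- lapply(profiles, function(p)
    tryCatch(auto_guinier(p), error = function(e) NULL))
  qmin <- vapply(gfits, function(g)
    if (!is.null(g) && isTRUE(g$valid)) g$q_range[1] else NA_real_, numeric(1))
  res <- sas_combine(profiles, grid, filter = filter, qmin = qmin, ...)
  res$guinier_fits <- gfits
  res
}
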