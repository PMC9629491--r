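#' One-dimensional scattering profile
#'
#' Container for a buffer-subtracted 1-D small-angle scattering measurement:
#' momentum transfer \code{q} (1/Angstrom), intensity \code{I} (arbitrary
#' units) and its standard error \code{sigma}, with an optional q-resolution
#' column \code{dq} (SANS) and free-form metadata.
#'
#' Invariants enforced at construction: \code{q} strictly increasing and
#' positive; equal lengths of all columns; \code{sigma > 0} everywhere.
#' Negative intensities are allowed (subtracted data near background).
#'
#' @param q numeric vector of momentum transfer values (1/Angstrom),
#'   strictly increasing, all positive.
#' @param I numeric vector of intensities (arbitrary units).
#' @param sigma numeric vector of standard errors of \code{I}; all positive.
#' @param dq optional numeric vector of q-resolution values (1/Angstrom).
#' @param meta named list of metadata (label, radiation, solvent_d2o_fraction,
#'   concentration, mode, instrument, header lines...). Free-form.
#' @return An object of class \code{"sas_profile"}: a list with elements
#'   \code{q}, \code{I}, \code{sigma}, optionally \code{dq}, and \code{meta}.
#' @examples
#' p <- sas_profile(q = c(0.01, 0.02), I = c(100, 90), sigma = c(1, 1))
#' print(p)
#' @export
sas_profile <- function(q, I, sigma, dq = NULL, meta = list()) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  n <- length(q)
  if (length(I) != n || length(sigma) != n)
    stop("q, I and sigma must have equal length")
  if (!is.null(dq)) {
    dq <- as.numeric(dq)
    if (length(dq) != n) stop("dq must have the same length as q")
  }
  if (n == 0L) stop("empty profile: no data points")
  if (any(!is.finite(q)) || any(!is.finite(I)) || any(!is.finite(sigma)))
    stop("non-finite values in profile columns")
  if (any(q <= 0)) stop("all q must be > 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma <= 0)) stop("all sigma must be > 0")
  structure(list(q = q, I = I, sigma = sigma, dq = dq, meta = meta),
            class = "sas_profile")
}

#' @export
print.sas_profile <- function(x, ...) {
  lab <- if (!is.null(x$meta$label)) paste0(" '", x$meta$label, "'") else ""
  cat(sprintf("Scattering profile%s: %d points, q = [%g, %g] 1/A\n",
              lab, length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$dq)) cat("  with q-resolution column (dq)\n")
  if (!is.null(x$meta$radiation))
    cat(sprintf("  radiation: %s\n", x$meta$radiation))
  invisible(x)
}

#' @export
length.sas_profile <- function(x) length(x$q)

#' @export
as.data.frame.sas_profile <- function(x, ...) {
  d <- data.frame(q = x$q, I = x$I, sigma = x$sigma)
  if (!is.null(x$dq)) d$dq <- x$dq
  d
}

#' @export
plot.sas_profile <- function(x, log = "y", ...) {
  ylab <- "I(q) (arbitrary units)"
  I <- x$I
  if (grepl("y", log)) {
    keep <- I > 0
    graphics::plot(x$q[keep], I[keep], log = log, xlab = "q (1/A)",
                   ylab = ylab, type = "l", ...)
  } else {
    graphics::plot(x$q, I, xlab = "q (1/A)", ylab = ylab, type = "l", ...)
  }
  invisible(x)
}

# Internal: subset a profile by a logical or integer index, keeping metadata.
profile_subset <- function(p, idx) {
  sas_profile(p$q[idx], p$I[idx], p$sigma[idx],
              dq = if (!is.null(p$dq)) p$dq[idx] else NULL, meta = p$meta)
}

#' Read a scattering profile from a plain-text file
#'
#' Reads whitespace-separated column files as deposited by SAS beamlines
#' (ATSAS-style \code{.dat}): optional header/comment lines followed by rows of
#' \code{q I sigma} and, for SANS, a fourth \code{dq} column. A six-column
#' dialect (\code{q I sigma dq ...}) is read as four columns with the trailing
#' columns ignored and logged.
#'
#' Non-numeric lines and lines starting with \code{#} are skipped and kept in
#' \code{meta$header}. Rows with non-finite values or \code{sigma <= 0} are
#' dropped; the number dropped is recorded in \code{meta$n_dropped}.
#'
#' @param path path to the text file.
#' @param dialect one of \code{"auto"}, \code{"three_col"}, \code{"four_col"},
#'   \code{"six_col"}. \code{"auto"} counts numeric columns of the first data
#'   row (3, 4 or 6).
#' @param q_scale multiplicative factor applied to the q column on read
#'   (e.g. \code{0.1} to convert a file in 1/nm to 1/Angstrom).
#' @return A \code{\link{sas_profile}}.
#' @export
read_profile <- function(path, dialect = c("auto", "three_col", "four_col", "six_col"),
                         q_scale = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty profile: no rows in ", path)

  toks <- strsplit(trimws(lines), "[[:space:],]+")
  nums <- lapply(toks, function(tk) suppressWarnings(as.numeric(tk)))
  is_data <- vapply(seq_along(lines), function(i) {
    !startsWith(trimws(lines[i]), "#") &&
      length(nums[[i]]) >= 2L && !anyNA(nums[[i]])
  }, logical(1))
  header <- lines[!is_data]
  rows <- nums[is_data]
  if (length(rows) == 0L)
    stop("format error in ", path, ": no numeric data rows; first line: ",
         lines[1])

  ncols <- vapply(rows, length, integer(1))
  nc0 <- ncols[1]
  if (dialect == "auto") {
    dialect <- switch(as.character(nc0),
                      "2" = stop("format error in ", path,
                                 ": need at least 3 columns (q I sigma), found 2"),
                      "3" = "three_col", "4" = "four_col", "6" = "six_col",
                      if (nc0 > 4) "six_col"
                      else stop("format error in ", path, ": unsupported column count ",
                                nc0, " in line: ", lines[is_data][1]))
  }
  need <- switch(dialect, three_col = 3L, four_col = 4L, six_col = 4L)
  bad <- which(ncols < need)
  if (length(bad))
    stop("format error in ", path, ": line with too few columns: ",
         lines[is_data][bad[1]])
  m <- t(vapply(rows, function(r) r[seq_len(need)], numeric(need)))
  q <- m[, 1] * q_scale; I <- m[, 2]; sig <- m[, 3]
  dq <- if (need == 4L) m[, 4] * q_scale else NULL

  ok <- is.finite(q) & is.finite(I) & is.finite(sig) & sig > 0 & q > 0
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("empty profile: no valid rows survive filtering in ", path)
  q <- q[ok]; I <- I[ok]; sig <- sig[ok]
  if (!is.null(dq)) dq <- dq[ok]
  o <- order(q)
  if (anyDuplicated(q[o])) {
    keep <- !duplicated(q[o])
    o <- o[keep]
  }
  meta <- list(path = path, header = header, n_dropped = n_dropped,
               dialect = dialect)
  if (dialect == "six_col" && nc0 > 4)
    meta$ignored_trailing_columns <- nc0 - 4L
  sas_profile(q[o], I[o], sig[o], dq = if (!is.null(dq)) dq[o] else NULL,
              meta = meta)
}

#' Write a scattering profile to a plain-text file
#'
#' Writes a '#'-prefixed header followed by whitespace-separated
#' \code{q I sigma} columns (plus \code{dq} if present), with enough digits
#' that \code{read_profile(write_profile(p))} reproduces the profile to better
#' than 1e-6 relative.
#'
#' @param profile a \code{\link{sas_profile}}.
#' @param path output file path.
#' @param digits significant digits to write (default 9).
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path, digits = 9) {
  stopifnot(inherits(profile, "sas_profile"))
  hdr <- c(sprintf("# %s", if (!is.null(profile$meta$label)) profile$meta$label
                   else "scattering profile"),
           if (is.null(profile$dq)) "# q(1/A) I sigma" else "# q(1/A) I sigma dq")
  fmt <- function(v) formatC(v, digits = digits, format = "g", width = -1)
  cols <- list(fmt(profile$q), fmt(profile$I), fmt(profile$sigma))
  if (!is.null(profile$dq)) cols <- c(cols, list(fmt(profile$dq)))
  body <- do.call(paste, c(cols, sep = " "))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Subtract a solvent (buffer) profile from a sample profile
#'
#' Computes the buffer-subtracted curve [Sample + Solvent] - [Solvent]:
#' \code{I = I_sample - scale * I_solvent} with errors added in quadrature,
#' \code{sigma = sqrt(sigma_sample^2 + scale^2 * sigma_solvent^2)}.
#' Both profiles must be on the same q-grid (to 1e-9 relative); rebin first
#' if they are not.
#'
#' @param sample,solvent \code{\link{sas_profile}} objects on identical q-grids.
#' @param scale positive scale applied to the solvent intensity (default 1).
#' @return A \code{\link{sas_profile}} with the sample's metadata.
#' @export
subtract_solvent <- function(sample, solvent, scale = 1) {
  stopifnot(inherits(sample, "sas_profile"), inherits(solvent, "sas_profile"))
  if (scale <= 0) stop("scale must be > 0")
  if (length(sample$q) != length(solvent$q) ||
      any(abs(sample$q - solvent$q) > 1e-9 * pmax(sample$q, solvent$q)))
    stop("grid mismatch between sample and solvent: rebin both onto a common q-grid first")
  sas_profile(sample$q,
              sample$I - scale * solvent$I,
              sqrt(sample$sigma^2 + scale^2 * solvent$sigma^2),
              dq = sample$dq, meta = sample$meta)
}
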