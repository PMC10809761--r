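# Mass isotopomer distributions: normalization, the natural-abundance
# convolution model, its non-negative inverse, and fractional enrichment.

#' Construct a mass isotopomer distribution
#'
#' A MID holds the fractional abundances of the isotopologues M+0..M+n of
#' one n-carbon analyte. Fractions must be non-negative and sum to one
#' (within 1e-9).
#'
#' @param fractions Numeric vector of length `n_carbons + 1`.
#' @param analyte Analyte name.
#' @param corrected Logical; `TRUE` once the natural 13C background has been
#'   removed (i.e. the MID is in the tracer-only, excess-label frame).
#' @param normalize If `TRUE`, rescale to sum exactly one before validating.
#' @return An object of class `"mid"`.
#' @export
mid <- function(fractions, analyte = NA_character_, corrected = FALSE,
                normalize = FALSE) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 2L) stop("a MID needs at least one carbon (length >= 2)")
  if (any(!is.finite(fractions))) stop("MID fractions must be finite")
  if (any(fractions < -1e-12)) stop("MID fractions must be non-negative")
  fractions <- pmax(fractions, 0)
  if (normalize) {
    s <- sum(fractions)
    if (s <= 0) stop("cannot normalize an all-zero MID")
    fractions <- fractions / s
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("MID fractions must sum to 1 (got %.12f)", sum(fractions)))
  }
  names(fractions) <- paste0("M+", seq_along(fractions) - 1L)
  structure(
    list(analyte = analyte, fractions = fractions,
         n_carbons = length(fractions) - 1L, corrected = isTRUE(corrected)),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s, %d carbons, %s\n",
              ifelse(is.na(x$analyte), "(unnamed)", x$analyte), x$n_carbons,
              if (x$corrected) "natural abundance removed" else "as measured"))
  print(round(x$fractions, 6))
  invisible(x)
}

#' @export
as.numeric.mid <- function(x, ...) unname(x$fractions)

#' Normalize isotopologue areas to a MID
#'
#' @param areas An `isotopologue_areas` object from
#'   [extract_isotopologue_areas()], or a bare numeric vector of areas
#'   a0..an.
#' @param analyte Analyte name (taken from `areas` when available).
#' @return An uncorrected [mid()].
#' @export
normalize_mid <- function(areas, analyte = NULL) {
  if (inherits(areas, "isotopologue_areas")) {
    if (is.null(analyte)) analyte <- areas$analyte
    areas <- areas$areas
  }
  areas <- as.numeric(areas)
  if (any(areas < 0)) stop("areas must be non-negative")
  if (sum(areas) <= 0) stop("all-zero area vector: analyte not detected")
  if (is.null(analyte)) analyte <- NA_character_
  mid(areas / sum(areas), analyte = analyte, corrected = FALSE)
}

#' Natural-abundance MID of an n-carbon analyte
#'
#' Carbon-only binomial model: each of the n carbons is 13C independently
#' with probability `p13`. Isotopes of H, N, O and S are not modelled; at
#' the resolution considered here the printed natural-abundance columns of
#' amino-acid MID tables match the carbon-only binomial to every digit.
#'
#' @param n_carbons Number of carbons (>= 1).
#' @param p13 Natural 13C abundance; default 0.011.
#' @return An uncorrected [mid()] with `f_k = C(n,k) p^k (1-p)^(n-k)`.
#' @export
natural_mid <- function(n_carbons, p13 = 0.011) {
  stopifnot(n_carbons >= 1)
  .check_p13(p13)
  mid(stats::dbinom(0:n_carbons, n_carbons, p13), corrected = FALSE)
}

.check_p13 <- function(p13) {
  if (!is.numeric(p13) || length(p13) != 1L || p13 < 0 || p13 >= 0.5) {
    stop("p13 must be a single probability in [0, 0.5)")
  }
  invisible(p13)
}

#' Natural-abundance convolution matrix
#'
#' Lower-triangular matrix A with
#' `A[k+1, j+1] = C(n-j, k-j) p^(k-j) (1-p)^(n-k)`: the probability that an
#' analyte with j tracer-labeled carbons is measured as M+k after each of
#' its n-j unlabeled carbons independently carries natural 13C. Columns sum
#' to one (truncation at M+n is complete), so the matrix maps the simplex
#' to itself.
#'
#' @inheritParams natural_mid
#' @return `(n+1) x (n+1)` lower-triangular matrix.
#' @export
na_matrix <- function(n_carbons, p13 = 0.011) {
  .check_p13(p13)
  n <- n_carbons
  A <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    A[(j:n) + 1L, j + 1L] <- stats::dbinom(0:(n - j), n - j, p13)
  }
  A
}

#' Convolve a tracer-only MID with natural abundance
#'
#' Forward model mapping the true (tracer-only) MID to the MID an
#' instrument measures: already-labeled carbons cannot gain, each remaining
#' carbon picks up natural 13C independently.
#'
#' @param true_mid A [mid()] in the tracer-only frame (or numeric vector).
#' @inheritParams natural_mid
#' @return An uncorrected (measured-frame) [mid()].
#' @export
convolve_natural <- function(true_mid, p13 = 0.011) {
  v <- if (inherits(true_mid, "mid")) unname(true_mid$fractions) else as.numeric(true_mid)
  analyte <- if (inherits(true_mid, "mid")) true_mid$analyte else NA_character_
  A <- na_matrix(length(v) - 1L, p13)
  mid(drop(A %*% v), analyte = analyte, corrected = FALSE)
}

#' Remove the natural 13C background from a measured MID
#'
#' Solves `measured = A %*% true` for the tracer-only MID, where A is the
#' lower-triangular binomial matrix of [na_matrix()]. The default solver is
#' non-negative least squares followed by renormalization, so that noisy
#' spectra cannot produce negative fractions; the plain triangular
#' inversion is retained as `method = "inverse"` and serves as an internal
#' cross-check on noiseless data.
#'
#' @param measured_mid A measured [mid()] (or numeric vector).
#' @inheritParams natural_mid
#' @param method `"nnls"` (default) or `"inverse"` (exact triangular solve,
#'   may go negative on noisy input; clipped and renormalized).
#' @param residual_tol Residual 2-norm above which the result is flagged as
#'   an inconsistent spectrum (attribute `consistent` set to `FALSE` with a
#'   warning).
#' @return A corrected [mid()] with attributes `residual` (2-norm of
#'   `A %*% true - measured` before renormalization) and `consistent`.
#' @export
correct_mid <- function(measured_mid, p13 = 0.011,
                        method = c("nnls", "inverse"), residual_tol = 0.01) {
  method <- match.arg(method)
  v <- if (inherits(measured_mid, "mid")) unname(measured_mid$fractions) else as.numeric(measured_mid)
  analyte <- if (inherits(measured_mid, "mid")) measured_mid$analyte else NA_character_
  A <- na_matrix(length(v) - 1L, p13)
  if (method == "nnls") {
    sol <- pracma::lsqnonneg(A, v)
    x <- sol$x
    residual <- sqrt(sum((A %*% x - v)^2))
  } else {
    x <- forwardsolve(A, v)
    residual <- sqrt(sum(pmin(x, 0)^2)) # exact solve: misfit lives in negativity
    x <- pmax(x, 0)
  }
  if (sum(x) <= 0) stop("correction yielded an all-zero MID")
  out <- mid(x / sum(x), analyte = analyte, corrected = TRUE)
  consistent <- residual <= residual_tol
  if (!consistent) {
    warning(sprintf("inconsistent spectrum for %s: correction residual %.3g > %.3g",
                    ifelse(is.na(analyte), "(unnamed)", analyte), residual, residual_tol))
  }
  attr(out, "residual") <- residual
  attr(out, "consistent") <- consistent
  out
}

#' Fractional enrichment (mean fraction of labeled carbons)
#'
#' @param x A [mid()] or numeric fraction vector f0..fn.
#' @return `sum(k * f_k) / n`, in `[0, 1]`.
#' @export
enrichment <- function(x) {
  v <- if (inherits(x, "mid")) unname(x$fractions) else as.numeric(x)
  n <- length(v) - 1L
  sum((0:n) * v) / n
}

#' Tidy MID table
#'
#' Flattens a list of MIDs into a long table mirroring the layout of
#' published MID tables: one row per analyte and isotopologue.
#'
#' @param mids Named list of [mid()] objects (names override analyte slots
#'   when the latter are missing).
#' @param condition,replicate Optional labels recycled across rows.
#' @param digits Rounding for the percent column (half-up, 2 decimals by
#'   default, matching printed tables).
#' @return `data.frame` with columns `analyte`, `isotopologue`, `condition`,
#'   `replicate`, `abundance_percent`, `corrected`.
#' @export
mid_table <- function(mids, condition = NA_character_, replicate = NA_integer_,
                      digits = 2) {
  if (inherits(mids, "mid")) mids <- list(mids)
  rows <- lapply(seq_along(mids), function(i) {
    m <- mids[[i]]
    analyte <- if (!is.na(m$analyte)) m$analyte else names(mids)[i]
    data.frame(
      analyte = analyte,
      isotopologue = names(m$fractions),
      condition = condition,
      replicate = replicate,
      abundance_percent = round_half_up(100 * unname(m$fractions), digits),
      corrected = m$corrected,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Round half away from zero
#'
#' Printed MID tables use conventional half-up rounding, not banker's
#' rounding; used whenever the package reproduces a printed percentage.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
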