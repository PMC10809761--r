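# Chemical reference layer: elemental formulas, monoisotopic masses,
# protonated m/z, ppm errors, and the amino-acid fragment carbon partition.

# Monoisotopic masses of the lightest isotope, Da (IUPAC). Hard-coded so the
# package never performs an external lookup at run time.
.monoisotopic_masses <- c(
  C = 12.0,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117
)

#' Mass of a proton in Da (charge +1 convention, no electron-mass refinement).
#' @keywords internal
.proton_mass <- 1.007276

#' Mass difference between 13C and 12C in Da; the isotopologue spacing on the
#' m/z axis at charge +1.
#' @keywords internal
.c13_spacing <- 1.003355

#' Parse an elemental formula
#'
#' Converts a Hill-style formula string such as `"C3H7NO3"` into a named
#' integer vector of element counts. Only C, H, N, O and S are accepted:
#' these cover all proteinogenic amino acids, and restricting the alphabet
#' turns typos into immediate errors rather than silent mass shifts.
#'
#' @param formula A formula string (e.g. `"C5H9NO4"`), or an already-parsed
#'   named numeric vector, which is validated and returned as integers.
#' @return Named integer vector of element counts with at least one atom.
#' @examples
#' parse_formula("C3H7NO3")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("numeric formula must be a named vector of element counts")
    }
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
      stop("formula must be a single non-empty string")
    }
    tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE))[[1]]
    if (sum(nchar(parts)) != nchar(formula)) {
      stop(sprintf("cannot parse formula '%s'", formula))
    }
    sym <- sub("[0-9]*$", "", parts)
    num <- sub("^[A-Za-z]+", "", parts)
    num <- ifelse(nzchar(num), as.integer(num), 1L)
    counts <- tapply(num, sym, sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.monoisotopic_masses))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("element counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("formula must contain at least one atom")
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of a neutral molecule
#'
#' Sum over elements of count times the exact mass of the lightest isotope.
#'
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C2H5NO2") # glycine, 75.032028
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .monoisotopic_masses[names(counts)])
}

#' Protonated m/z of a molecule at charge +1
#'
#' Positive-mode CE-MS of amino acids in an acidic background electrolyte
#' yields singly protonated ions; no multimers or adducts are modelled.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Th for the `[M+H]+` ion.
#' @examples
#' protonated_mz("C3H7NO3") # serine, 106.049869
#' @export
protonated_mz <- function(formula) {
  monoisotopic_mass(formula) + .proton_mass
}

#' Signed mass error in parts per million
#'
#' @param theoretical Theoretical m/z (Th), must be positive.
#' @param observed Observed m/z (Th).
#' @return Signed ppm deviation `1e6 * (observed - theoretical) / theoretical`.
#'   Reporting layers may take the absolute value.
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical m/z must be positive and finite")
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Theoretical m/z of the side-chain (immonium-type) fragment
#'
#' HCD fragmentation of protonated amino acids proceeds predominantly by
#' combined loss of H2O and CO from the carboxyl group, yielding the
#' immonium ion that retains carbons C2..Cn. This is the fragment used for
#' the main-chain/side-chain positional split: the carboxyl carbon C1 is
#' the only carbon lost.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Th of the unlabeled fragment ion.
#' @export
fragment_mz <- function(formula) {
  # neutral loss H2O + CO = CH2O2 (formic acid equivalent)
  loss <- monoisotopic_mass(c(C = 1, H = 2, O = 2))
  protonated_mz(formula) - loss
}

#' Amino-acid reference table
#'
#' Loads the bundled reference of the 20 proteinogenic amino acids: neutral
#' formula, carbon count, the main-chain/side-chain carbon partition used
#' for positional isotopomer analysis, a nominal migration time from a
#' standard mixture, and detectability after acid hydrolysis (Cys and Trp
#' are degraded by 12 N HCl; Asn and Gln deamidate to Asp and Glu, leaving
#' 16 detectable analytes).
#'
#' The partition assigns the carboxyl carbon C1 as the main chain and
#' C2..Cn as the side chain, matching the immonium-type fragmentation in
#' which only C1 is lost (see [fragment_mz()]).
#'
#' @param path Optional path to a user-supplied delimited reference table
#'   with the same columns; defaults to the bundled file.
#' @param detectable_only If `TRUE`, keep only analytes that survive acid
#'   hydrolysis.
#' @return A `data.frame` with columns `name`, `code`, `formula`,
#'   `n_carbons`, `main_indices`, `side_indices`, `detectable`,
#'   `migration_time_s`, plus derived columns `mz` (protonated) and
#'   `frag_mz` (side-chain fragment).
#' @export
amino_acid_specs <- function(path = NULL, detectable_only = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "amino_acids.csv", package = "tracemid", mustWork = TRUE)
  }
  specs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "code", "formula", "n_carbons", "main_indices",
                "side_indices", "detectable", "migration_time_s")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0L) {
    stop(sprintf("amino-acid reference is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  specs$detectable <- as.logical(specs$detectable)
  specs$main_indices <- as.character(specs$main_indices)
  specs$side_indices <- as.character(specs$side_indices)
  specs$mz <- vapply(specs$formula, protonated_mz, numeric(1))
  specs$frag_mz <- vapply(specs$formula, fragment_mz, numeric(1))
  validate_aa_specs(specs)
  if (detectable_only) specs <- specs[specs$detectable, , drop = FALSE]
  rownames(specs) <- NULL
  specs
}

#' @keywords internal
.parse_indices <- function(s) {
  s <- as.character(s)
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Validate an amino-acid reference table
#'
#' Enforces the partition invariants: main and side index sets are disjoint,
#' their union is 1..n_carbons, and the main chain is non-empty.
#'
#' @param specs A reference table as returned by [amino_acid_specs()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_aa_specs <- function(specs) {
  for (i in seq_len(nrow(specs))) {
    main <- .parse_indices(specs$main_indices[i])
    side <- .parse_indices(specs$side_indices[i])
    n <- specs$n_carbons[i]
    who <- specs$code[i]
    counts <- parse_formula(specs$formula[i])
    if (is.na(counts["C"]) || counts[["C"]] != n) {
      stop(sprintf("%s: n_carbons (%d) disagrees with formula %s", who, n, specs$formula[i]))
    }
    if (length(main) < 1L) stop(sprintf("%s: main chain must contain at least one carbon", who))
    if (length(intersect(main, side)) > 0L) {
      stop(sprintf("%s: main and side chain carbon sets overlap", who))
    }
    if (!setequal(union(main, side), seq_len(n))) {
      stop(sprintf("%s: main and side chains must partition carbons 1..%d", who, n))
    }
  }
  invisible(specs)
}
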