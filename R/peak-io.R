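# Peak-list ingestion, accurate-mass + migration-time annotation, and
# isotopologue area extraction.

#' Read a peak list from delimited text
#'
#' Precursor-level peak lists carry columns `sample_id`, `mz`, `area`,
#' `migration_time_s`; fragment-level lists additionally carry
#' `precursor_name` and `precursor_isotopologue` (the M+k index of the
#' precursor that was isolated for MS/MS). Files are UTF-8,
#' comma-delimited, dot-decimal, with a mandatory header row.
#'
#' @param path Path to the CSV file.
#' @param level `"precursor"` or `"fragment"`.
#' @return A `data.frame` of class `"peaklist"` with attribute `level`;
#'   row order is preserved. A header-only file yields an empty peak list
#'   with a warning.
#' @export
read_peaklist <- function(path, level = c("precursor", "fragment")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop(sprintf("peak list file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("sample_id", "mz", "area", "migration_time_s")
  if (level == "fragment") required <- c(required, "precursor_name", "precursor_isotopologue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  numeric_cols <- c("mz", "area", "migration_time_s",
                    if (level == "fragment") "precursor_isotopologue")
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(df[[col]])))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric value in column '%s' at data line %s",
                   path, col, paste(bad, collapse = ", ")))
    }
    df[[col]] <- vals
  }
  if (nrow(df) == 0L) warning(sprintf("%s: header-only file, empty peak list", path))
  if (any(df$mz <= 0, na.rm = TRUE)) stop(sprintf("%s: m/z values must be positive", path))
  if (any(df$area < 0, na.rm = TRUE)) stop(sprintf("%s: areas must be non-negative", path))
  as_peaklist(df, level = level)
}

#' @rdname read_peaklist
#' @param df A data.frame with the columns described above.
#' @export
as_peaklist <- function(df, level = c("precursor", "fragment")) {
  level <- match.arg(level)
  structure(df, class = c("peaklist", "data.frame"), level = level)
}

#' Write a peak list to delimited text
#'
#' Inverse of [read_peaklist()]; write-then-read round-trips the records.
#'
#' @param peaks A `peaklist`.
#' @param path Output path.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign amino acids to peaks by accurate mass and migration time
#'
#' For each analyte in the reference table, candidate peaks are those
#' within `ppm_tol` of the protonated theoretical m/z and (when a reference
#' migration time is available) within `mt_window` seconds of it; the
#' highest-area candidate wins. Analytes with identical masses (Leu/Ile)
#' are disambiguated purely by the migration-time window, mirroring their
#' electrophoretic separation. When two analytes claim the same peak the
#' tie is broken by smaller absolute ppm error, then larger area, and the
#' loser falls back to its next-best candidate.
#'
#' @param peaks A precursor-level `peaklist`.
#' @param specs Amino-acid reference table ([amino_acid_specs()]).
#' @param ppm_tol Mass tolerance in ppm (> 0). Default 5 ppm.
#' @param mt_window Migration-time half-window in seconds; `Inf` disables
#'   the time filter. Default 6 s.
#' @return A `data.frame` with one row per analyte in `specs`: `analyte`,
#'   `theoretical_mz`, `observed_mz`, `ppm_error`, `migration_time`,
#'   `area`, `matched` (logical), `peak_row` (row index into `peaks`).
#'   Unmatched analytes have `matched = FALSE` and `NA` observations.
#' @export
match_amino_acids <- function(peaks, specs, ppm_tol = 5, mt_window = 6) {
  stopifnot(ppm_tol > 0)
  n <- nrow(specs)
  candidates <- vector("list", n)
  for (i in seq_len(n)) {
    dppm <- ppm_error(specs$mz[i], peaks$mz)
    keep <- abs(dppm) <= ppm_tol
    if (is.finite(mt_window) && !is.na(specs$migration_time_s[i])) {
      keep <- keep & abs(peaks$migration_time_s - specs$migration_time_s[i]) <= mt_window
    }
    idx <- which(keep)
    if (length(idx) > 0L) {
      ord <- order(-peaks$area[idx], abs(dppm[idx]))
      candidates[[i]] <- data.frame(row = idx[ord], ppm = dppm[idx][ord],
                                    area = peaks$area[idx][ord])
    } else {
      candidates[[i]] <- data.frame(row = integer(0), ppm = numeric(0), area = numeric(0))
    }
  }
  assigned <- rep(NA_integer_, n)   # chosen candidate rank per spec
  claimed <- integer(0)             # peak rows already taken
  # greedy resolution: repeatedly give each spec its best unclaimed candidate,
  # settling conflicts by |ppm| then area
  for (pass in seq_len(n)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!is.na(assigned[i])) next
      cand <- candidates[[i]]
      cand <- cand[!(cand$row %in% claimed), , drop = FALSE]
      if (nrow(cand) == 0L) next
      pick <- cand[1L, ]
      # does another unassigned spec want this same peak with a better claim?
      contested <- FALSE
      for (j in seq_len(n)) {
        if (j == i || !is.na(assigned[j])) next
        cj <- candidates[[j]]
        cj <- cj[!(cj$row %in% claimed), , drop = FALSE]
        if (nrow(cj) == 0L || cj$row[1L] != pick$row) next
        better <- abs(cj$ppm[1L]) < abs(pick$ppm) ||
          (abs(cj$ppm[1L]) == abs(pick$ppm) && cj$area[1L] > pick$area)
        if (better) contested <- TRUE
      }
      if (!contested) {
        assigned[i] <- pick$row
        claimed <- c(claimed, pick$row)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- data.frame(
    analyte = specs$code,
    theoretical_mz = specs$mz,
    observed_mz = NA_real_,
    ppm_error = NA_real_,
    migration_time = NA_real_,
    area = NA_real_,
    matched = FALSE,
    peak_row = NA_integer_,
    stringsAsFactors = FALSE
  )
  hit <- !is.na(assigned)
  out$peak_row[hit] <- assigned[hit]
  out$observed_mz[hit] <- peaks$mz[assigned[hit]]
  out$ppm_error[hit] <- ppm_error(specs$mz[hit], peaks$mz[assigned[hit]])
  out$migration_time[hit] <- peaks$migration_time_s[assigned[hit]]
  out$area[hit] <- peaks$area[assigned[hit]]
  out$matched <- hit
  out
}

#' Extract isotopologue areas M+0..M+n for one matched analyte
#'
#' For each k in 0..n the peak nearest to `observed_mz + k * 1.003355` Th
#' within `ppm_tol` (and within `mt_window` of the matched migration time)
#' contributes its area; absent isotopologues are zeros with
#' `detected = FALSE`, mirroring "not detected" entries in published
#' tables. The spacing is the 13C-12C mass difference, not unity: at
#' m/z ~ 106 a peak placed at +1.000 Th is ~32 ppm away and is not
#' collected.
#'
#' @param peaks A precursor-level `peaklist`.
#' @param match One row of the output of [match_amino_acids()] (must have
#'   `matched = TRUE`).
#' @param n_carbons Number of carbons of the analyte.
#' @param ppm_tol Mass tolerance in ppm.
#' @param mt_window Migration-time half-window in seconds.
#' @return An object of class `"isotopologue_areas"`: list with `analyte`,
#'   `areas` (length n+1), `ppm` (per-isotopologue match error, NA when
#'   absent), `detected` (logical), `migration_time`.
#' @export
extract_isotopologue_areas <- function(peaks, match, n_carbons, ppm_tol = 5,
                                       mt_window = 6) {
  if (!isTRUE(match$matched)) stop(sprintf("analyte %s was not matched", match$analyte))
  anchor <- match$observed_mz
  areas <- numeric(n_carbons + 1L)
  ppm <- rep(NA_real_, n_carbons + 1L)
  detected <- logical(n_carbons + 1L)
  in_time <- if (is.finite(mt_window)) {
    abs(peaks$migration_time_s - match$migration_time) <= mt_window
  } else rep(TRUE, nrow(peaks))
  for (k in 0:n_carbons) {
    target <- anchor + k * .c13_spacing
    dppm <- ppm_error(target, peaks$mz)
    ok <- which(abs(dppm) <= ppm_tol & in_time)
    if (length(ok) > 0L) {
      best <- ok[which.min(abs(dppm[ok]))]
      areas[k + 1L] <- peaks$area[best]
      ppm[k + 1L] <- dppm[best]
      detected[k + 1L] <- TRUE
    }
  }
  structure(
    list(analyte = match$analyte, areas = areas, ppm = ppm,
         detected = detected, migration_time = match$migration_time),
    class = "isotopologue_areas"
  )
}

#' Aggregate side-chain fragment areas into a fragment MID's raw areas
#'
#' Fragment peak lists record, for each isolated precursor isotopologue,
#' the fragment spectrum of the side-chain (immonium-type) ion. Fragment
#' isotopologue areas are summed over precursor isotopologues, giving the
#' raw area vector of the side-chain fragment M+0..M+n_side.
#'
#' @param frag_peaks A fragment-level `peaklist`.
#' @param spec One row of the amino-acid reference (needs `code`,
#'   `frag_mz`, `n_carbons`, side-chain size inferred as `n_carbons - 1`).
#' @param ppm_tol Mass tolerance in ppm.
#' @return An `"isotopologue_areas"` object over the side-chain carbons.
#' @export
extract_fragment_areas <- function(frag_peaks, spec, ppm_tol = 5) {
  rows <- frag_peaks[frag_peaks$precursor_name == spec$code, , drop = FALSE]
  n_side <- spec$n_carbons - length(.parse_indices(spec$main_indices))
  areas <- numeric(n_side + 1L)
  ppm <- rep(NA_real_, n_side + 1L)
  detected <- logical(n_side + 1L)
  if (nrow(rows) > 0L) {
    for (k in 0:n_side) {
      target <- spec$frag_mz + k * .c13_spacing
      dppm <- ppm_error(target, rows$mz)
      ok <- which(abs(dppm) <= ppm_tol)
      if (length(ok) > 0L) {
        areas[k + 1L] <- sum(rows$area[ok])
        ppm[k + 1L] <- stats::weighted.mean(dppm[ok], rows$area[ok])
        detected[k + 1L] <- TRUE
      }
    }
  }
  structure(
    list(analyte = paste0(spec$code, "_fragment"), areas = areas, ppm = ppm,
         detected = detected, migration_time = NA_real_),
    class = "isotopologue_areas"
  )
}
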