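# Bundled reference dataset: published CE-MS mass isotopomer distributions
# and MS/MS positional isotopomer splits of Ser, Asp and Glu from a 13C
# tracer study of the hydrogenotrophic methanogen Methanothermobacter
# thermautotrophicus (13CO2 spike, 13C-acetate co-feeds, negative controls,
# duplicate cultures). "Not detected" entries are encoded as NA.

#' Reference MID and positional tables
#'
#' `reference_mid_table()` returns the precursor-level mass isotopomer
#' distributions (percent abundances per analyte, condition and replicate);
#' `reference_positional_table()` the corresponding main-/side-chain
#' positional splits. Conditions: `"natural"` (theoretical natural
#' abundance, no replicate), `"13CO2"`, `"13CO2_acetate"` (13CO2 plus
#' unlabeled acetate), `"acetate_1"` (`[1-13C1]` acetate), `"acetate_2"`
#' (`[2-13C1]` acetate), `"control"`.
#'
#' @return Long `data.frame`s; abundances in percent, `NA` = not detected.
#' @export
reference_mid_table <- function() {
  utils::read.csv(system.file("extdata", "reference_mids.csv",
                              package = "tracemid", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_mid_table
#' @export
reference_positional_table <- function() {
  utils::read.csv(system.file("extdata", "reference_positional.csv",
                              package = "tracemid", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Measured-frame MIDs for one reference condition
#'
#' Convenience accessor turning one column of the reference MID table into
#' [mid()] objects. Not-detected entries become zero fractions, as an
#' undetected isotopologue contributes no area.
#'
#' @param condition One of the condition labels of
#'   [reference_mid_table()].
#' @param replicate Replicate number (ignored for `"natural"`).
#' @return Named list of uncorrected [mid()]s for Ser, Asp, Glu.
#' @export
reference_mids <- function(condition = "13CO2", replicate = 1) {
  tab <- reference_mid_table()
  if (!condition %in% tab$condition) {
    stop(sprintf("unknown condition '%s'", condition))
  }
  sel <- tab[tab$condition == condition &
               (is.na(tab$replicate) | tab$replicate == replicate), , drop = FALSE]
  out <- lapply(split(sel, sel$analyte), function(d) {
    d <- d[order(d$n_labels), ]
    v <- ifelse(is.na(d$abundance_percent), 0, d$abundance_percent)
    mid(v / sum(v), analyte = d$analyte[1], corrected = FALSE)
  })
  out[intersect(c("Ser", "Asp", "Glu"), names(out))]
}
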