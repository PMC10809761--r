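# MID bar plots: grouped isotopologue fractions per analyte/condition.

#' Grouped bar plot of mass isotopomer distributions
#'
#' One panel per analyte, bars for M+0..M+n grouped by condition/replicate,
#' the layout used to compare labeling across tracer experiments.
#'
#' @param tab A tidy table from [mid_table()] (possibly rbind-ed across
#'   conditions), or a named list of [mid()] objects.
#' @param percent Plot percent (default) or fractions.
#' @return A ggplot object.
#' @export
plot_mids <- function(tab, percent = TRUE) {
  if (!is.data.frame(tab)) tab <- mid_table(tab)
  tab$group <- ifelse(is.na(tab$condition), "sample",
                      paste(tab$condition,
                            ifelse(is.na(tab$replicate), "", tab$replicate)))
  y <- if (percent) tab$abundance_percent else tab$abundance_percent / 100
  tab$y <- y
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$isotopologue, y = .data$y,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::facet_wrap(~analyte, scales = "free_x") +
    ggplot2::labs(x = NULL, y = if (percent) "abundance (%)" else "fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
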