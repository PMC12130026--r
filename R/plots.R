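# ggplot2 views of screening and association results.

#' Bar chart of PIM flags by physiological system
#'
#' @param screen A `pim_screen`.
#' @return A ggplot object.
#' @export
plot_system_tally <- function(screen) {
  tl <- tally_flags(screen, by = "system")
  tl$system_group <- factor(tl$system_group, levels = rev(tl$system_group))
  ggplot2::ggplot(tl, ggplot2::aes(x = .data$n, y = .data$system_group)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "PIM instances", y = NULL,
                  title = "PIM flags by physiological system") +
    ggplot2::theme_minimal()
}

#' Bar chart of the most frequently flagged drugs
#'
#' @param screen A `pim_screen`.
#' @param top_k Number of drugs shown.
#' @return A ggplot object.
#' @export
plot_top_drugs <- function(screen, top_k = 10L) {
  td <- head(tally_flags(screen, by = "drug"), top_k)
  td$name <- factor(td$name, levels = rev(td$name))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$n, y = .data$name)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "flag instances naming the drug", y = NULL,
                  title = paste("Top", top_k, "inappropriately prescribed drugs")) +
    ggplot2::theme_minimal()
}

#' Forest plot of an odds-ratio table
#'
#' @param or_table A tidy odds-ratio tibble such as [tidy.pim_logit()]
#'   output (columns `level`, `odds_ratio`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_or_forest <- function(or_table) {
  or_table$label <- if ("term" %in% names(or_table)) {
    paste(or_table$term, or_table$level, sep = ": ")
  } else {
    or_table$level
  }
  or_table$label <- factor(or_table$label, levels = rev(or_table$label))
  ggplot2::ggplot(or_table,
                  ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot pim_screen
#' @export
autoplot.pim_screen <- function(object, ...) plot_system_tally(object)
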