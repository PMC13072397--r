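# Plot helpers ---------------------------------------------------------------

#' Plot a sliding-window nucleotide diversity track
#'
#' @param windows Tibble from [sliding_window_pi()] (optionally with a `gene`
#'   column for faceting, as written by the pipeline).
#' @return A ggplot object.
#' @export
plot_sliding_window <- function(windows) {
  p <- ggplot2::ggplot(windows, ggplot2::aes(x = .data$midpoint, y = .data$pi)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Alignment position (bp)", y = "Nucleotide diversity (Pi)") +
    ggplot2::theme_minimal()
  if ("gene" %in% names(windows)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x")
  }
  p
}

#' ENC plot against the mutation-bias expectation
#'
#' Scatter of ENC against GC3 with the null curve
#' `ENC = 2 + s + 29/(s^2 + (1-s)^2)`; species below the curve show codon
#' bias beyond composition alone.
#'
#' @param usage Tibble from [codon_usage()].
#' @return A ggplot object.
#' @export
plot_enc <- function(usage) {
  grid <- tibble::tibble(gc3 = seq(0.01, 0.99, by = 0.01))
  grid$enc <- enc_expected(grid$gc3)
  ggplot2::ggplot(usage, ggplot2::aes(x = .data$GC3_pct / 100, y = .data$ENC)) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$gc3, y = .data$enc),
      linetype = "dashed", color = "grey40"
    ) +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::labs(x = "GC3 (fraction)", y = "Effective number of codons (ENC)") +
    ggplot2::theme_minimal()
}

#' Boxplot of a variable across groups
#'
#' Companion to [group_compare()]: e.g. AT% across habitat classes.
#'
#' @param data Data frame.
#' @param value,group Column names (strings).
#' @return A ggplot object.
#' @export
plot_group_boxplot <- function(data, value, group) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[group]], y = .data[[value]], fill = .data[[group]]
  )) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Plot Bayes empirical Bayes site posteriors
#'
#' Per-site posterior probability of the positively selected classes, with the
#' conventional 0.95 threshold marked.
#'
#' @param beb_table Tibble from [beb()].
#' @return A ggplot object.
#' @export
plot_beb <- function(beb_table) {
  ggplot2::ggplot(beb_table, ggplot2::aes(x = .data$site, y = .data$pp)) +
    ggplot2::geom_col(width = 1, fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed", color = "grey30") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Codon site", y = "Posterior P(positive selection)") +
    ggplot2::theme_minimal()
}
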