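# ggplot2 helpers for the main result types.

#' Forest plot of reporting odds ratios
#'
#' Events on the y axis, ROR with its 95% interval on a log x axis;
#' signalled events highlighted.
#'
#' @param object a `signal_table` from [detect_signals()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.signal_table <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$ror))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror,
                                   y = stats::reorder(.data$event_pt, .data$ror),
                                   colour = .data$is_signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror025,
                                         xmax = .data$ror975), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reporting odds ratio (95% CI)", y = NULL,
                  colour = "signal") +
    ggplot2::theme_minimal()
}

#' Cumulative time-to-onset curves by group
#'
#' @param tto tibble from [compute_tto()].
#' @param group grouping column name.
#' @return A ggplot object (empirical CDF step curves).
#' @export
plot_tto_cdf <- function(tto, group) {
  df <- tto_cdf(tto, group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tto_days, y = .data$cdf,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time to onset (days)", y = "cumulative proportion",
                  colour = group) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of pathway-ROR Spearman correlations
#'
#' @param screen tibble from [screen_pathways()].
#' @return A ggplot object.
#' @export
plot_pathway_lollipop <- function(screen) {
  df <- dplyr::mutate(screen,
                      gene_set = stats::reorder(.data$gene_set, .data$rs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rs, y = .data$gene_set,
                                   colour = .data$sign)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rs,
                                       yend = .data$gene_set)) +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$p_value))) +
    ggplot2::scale_colour_manual(values = c(positive = "orange",
                                            negative = "darkgreen")) +
    ggplot2::labs(x = "Spearman Rs vs irAE ROR", y = NULL,
                  size = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Heat-grid of bivariate model performance
#'
#' Predictor pairs shaded by the Spearman correlation of predicted vs
#' observed RORs, sized by likelihood-ratio significance.
#'
#' @param object a `bivariate_search` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bivariate_search <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      min_lrt_p = pmin(.data$lrt_p_vs_x1, .data$lrt_p_vs_x2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rs_pred_obs,
                                     size = -log10(.data$min_lrt_p))) +
    ggplot2::scale_colour_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(colour = "Rs (pred vs obs)", size = "-log10 LRT p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
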