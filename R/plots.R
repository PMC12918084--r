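# Optional ggplot2 figures over the report tables.  The CSV tables are
# the contract; these are conveniences for the analysis scripts.

needs_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    hl_abort("ggplot2 is required for plotting", "hlmrp_config_error")
}

#' Forest plot of MRP-ATE summaries
#'
#' @param ate_summary the `ate` table of a `report_bundle`.
#' @return A ggplot object.
#' @export
plot_forest <- function(ate_summary) {
  needs_ggplot()
  df <- ate_summary
  df$label <- paste(df$variable, df$level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$label,
                                   colour = .data$outcome,
                                   shape = .data$outcome)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower95,
                                          xmax = .data$upper95),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::labs(x = "MRP-ATE (change in probability not health literate)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Rankogram of cumulative rank probabilities
#'
#' @param rankogram a rankogram table (`item`, `rank`,
#'   `cumulative_probability`, optionally `outcome`).
#' @return A ggplot object.
#' @export
plot_rankogram <- function(rankogram) {
  needs_ggplot()
  p <- ggplot2::ggplot(rankogram,
                       ggplot2::aes(x = .data$rank,
                                    y = .data$cumulative_probability,
                                    colour = .data$item,
                                    group = .data$item)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Rank", y = "Cumulative rank probability") +
    ggplot2::theme_minimal()
  if ("outcome" %in% names(rankogram))
    p <- p + ggplot2::facet_wrap(~outcome)
  p
}

#' Dumbbell plot of source vs target demographic proportions
#'
#' @param comparison table from [compare_demographics()].
#' @param outcome which outcome's source subsample to show.
#' @return A ggplot object.
#' @export
plot_dumbbell <- function(comparison, outcome = comparison$outcome[1]) {
  needs_ggplot()
  df <- comparison[comparison$outcome == outcome, ]
  df$label <- paste(df$variable, df$level)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$source_prop,
                                       xend = .data$target_prop,
                                       yend = .data$label),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$source_prop),
                        colour = "darkorange", size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$target_prop),
                        colour = "steelblue", shape = 1, size = 2) +
    ggplot2::labs(x = "Proportion", y = NULL,
                  subtitle = paste("source (solid) vs target (hollow),",
                                   outcome, "subsample")) +
    ggplot2::theme_minimal()
}
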