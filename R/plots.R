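#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col geom_errorbar geom_boxplot facet_wrap labs theme_minimal
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot a sensitivity study: mean counts against z
#'
#' Mean per-cell count per group across the z grid, one panel per cell
#' line, with significant hypotheses (Bonferroni) marked along the z axis.
#'
#' @param object A `punctaflux_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.punctaflux_sweep <- function(object, ...) {
  gm <- attr(object, "group_means")
  sig <- dplyr::filter(as_tibble(object), .data$significant)
  p <- ggplot(gm, aes(x = .data$z, y = .data$mean_count,
                      colour = .data$condition)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~cell_line) +
    labs(x = "detection threshold z",
         y = sprintf("mean %s per cell", attr(object, "response")),
         colour = "condition",
         caption = sprintf("ticks: p < alpha/m = %.2g (Kruskal-Wallis, m = %d)",
                           attr(object, "alpha") / attr(object, "m"),
                           attr(object, "m"))) +
    theme_minimal()
  if (nrow(sig)) {
    p <- p + geom_point(data = sig, aes(x = .data$z, y = 0),
                        inherit.aes = FALSE, shape = 3)
  }
  p
}

#' Plot per-cell puncta counts
#'
#' Bar chart of mean per-cell dual puncta (total and mitochondria-
#' associated) per condition, with standard-error bars.
#'
#' @param object A per-cell summary tibble (e.g.
#'   `run_pipeline(...)$cell_summaries`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_cell_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("n_dual", "n_dual_near_mito"),
                              names_to = "count", values_to = "value")
  stats_ <- long |>
    dplyr::group_by(.data$condition, .data$count) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot(stats_, aes(x = .data$condition, y = .data$mean,
                     fill = .data$count)) +
    geom_col(position = position_dodge(0.9)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(0.9), width = 0.25) +
    labs(x = NULL, y = "dual GFP-mRFP puncta per cell",
         fill = NULL) +
    theme_minimal()
}

#' Plot per-cell mitochondrial-potential ratio boxplots
#'
#' One box per cell and ratio definition, built from the precomputed
#' boxplot statistics; values below 1 indicate autophagosomes over
#' fainter-than-average (lower potential) mitochondria.
#'
#' @param object A `punctaflux_ratio_summary` from [summarize_ratios()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.punctaflux_ratio_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$cell_id)) +
    geom_boxplot(aes(ymin = .data$whisker_low, lower = .data$q1,
                     middle = .data$median, upper = .data$q3,
                     ymax = .data$whisker_high),
                 stat = "identity", width = 0.5) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    facet_wrap(~ratio) +
    labs(x = NULL, y = "mito intensity ratio under puncta") +
    theme_minimal()
}
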