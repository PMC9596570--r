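#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sensitivity-study result
#'
#' One row per hypothesis (cell line, condition pair, z) with the test
#' statistic, p-value and Bonferroni-corrected significance flag.
#'
#' @param x A `punctaflux_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.punctaflux_sweep <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Summarize a sensitivity-study result in one row
#'
#' @param x A `punctaflux_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return One-row tibble: `m`, `alpha`, `corrected_alpha`, `n_tested`,
#'   `n_significant`, `min_p`.
#' @export
glance.punctaflux_sweep <- function(x, ...) {
  tibble(m = attr(x, "m"), alpha = attr(x, "alpha"),
         corrected_alpha = attr(x, "alpha") / attr(x, "m"),
         n_tested = sum(!is.na(x$p_value)),
         n_significant = sum(x$significant, na.rm = TRUE),
         min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}

#' Tidy a pipeline run
#'
#' @param x A `punctaflux_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-cell summary tibble.
#' @export
tidy.punctaflux_run <- function(x, ...) x$cell_summaries

#' One-row overview of a pipeline run
#'
#' @param x A `punctaflux_run` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble with cell/frame counts and mean per-cell dual
#'   puncta.
#' @export
glance.punctaflux_run <- function(x, ...) {
  cs <- x$cell_summaries
  tibble(n_cells = length(unique(cs$cell_id)),
         n_frames = nrow(cs),
         n_skipped = nrow(x$skipped),
         mean_n_dual = mean(cs$n_dual),
         mean_fraction_near_mito = mean(cs$fraction_near_mito, na.rm = TRUE))
}
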