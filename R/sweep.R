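#' Configuration of the z-value sensitivity study
#'
#' The sensitivity study re-runs detection and association across a grid
#' of detection thresholds z and, at each z, compares per-cell counts
#' between every unordered pair of conditions within every cell line with
#' a Kruskal-Wallis test. The total number of hypotheses
#' `m = choose(n_conditions, 2) * n_cell_lines * n_z` is always computed,
#' never user-supplied, and each test is assessed at the Bonferroni level
#' `alpha / m`. The reference design (4 conditions, 2 cell lines, 21
#' z-values) gives m = 6 x 2 x 21 = 252.
#'
#' @param z_values Strictly increasing grid of z thresholds (default 21
#'   values spanning (0, 2]; thresholds above 2 empty the masks).
#' @param conditions Condition labels (unique, at least 2).
#' @param cell_lines Cell-line labels.
#' @param alpha Family significance level (default 0.05).
#' @param response Per-cell count compared across groups: `"n_dual"` or
#'   `"n_dual_near_mito"`.
#' @return A list of class `sweep_config` with the computed `m`.
#' @export
sweep_config <- function(z_values = seq(0.1, 2, length.out = 21),
                         conditions = c("DMSO", "DMSO+BafA1", "CCCP",
                                        "CCCP+BafA1"),
                         cell_lines = c("WT", "KO"),
                         alpha = 0.05, response = "n_dual") {
  stopifnot(all(z_values > 0), !is.unsorted(z_values, strictly = TRUE),
            length(conditions) >= 2, length(cell_lines) >= 1,
            alpha > 0, alpha < 1,
            response %in% c("n_dual", "n_dual_near_mito"))
  if (anyDuplicated(conditions)) abort("duplicate condition labels")
  m <- choose(length(conditions), 2) * length(cell_lines) * length(z_values)
  structure(list(z_values = z_values, conditions = conditions,
                 cell_lines = cell_lines, alpha = alpha,
                 response = response, m = m),
            class = "sweep_config")
}

#' Enumerate the hypothesis grid
#'
#' The Cartesian product of unordered condition pairs, cell lines and
#' z-values; its length is the Bonferroni denominator m.
#'
#' @param config A [sweep_config()].
#' @return A tibble with columns `cell_line`, `condition_a`,
#'   `condition_b`, `z`; `attr(, "m")` and `attr(, "corrected_alpha")`
#'   carry the family size and per-test level.
#' @export
build_hypothesis_grid <- function(config = sweep_config()) {
  pairs <- utils::combn(config$conditions, 2)
  grid <- tidyr::crossing(
    cell_line = config$cell_lines,
    pair = seq_len(ncol(pairs)),
    z = config$z_values) |>
    dplyr::mutate(condition_a = pairs[1, .data$pair],
                  condition_b = pairs[2, .data$pair]) |>
    dplyr::select("cell_line", "condition_a", "condition_b", "z")
  stopifnot(nrow(grid) == config$m)
  attr(grid, "m") <- config$m
  attr(grid, "corrected_alpha") <- config$alpha / config$m
  grid
}

#' Kruskal-Wallis test on per-cell counts
#'
#' Rank-based test that two or more groups of per-cell counts originate
#' from the same distribution: tie-corrected H statistic with a
#' chi-squared approximation on k - 1 degrees of freedom (via
#' [stats::kruskal.test()]). All-identical observations give H = 0,
#' p = 1.
#'
#' @param groups List of two or more numeric vectors.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) < 2) {
    return(tibble(statistic = 0, df = length(groups) - 1L, p_value = 1,
                  n = length(x)))
  }
  kt <- stats::kruskal.test(x, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(x))
}

# fast two-group path used inside the sweep loop
kruskal_hp <- function(a, b) {
  x <- c(a, b)
  if (length(unique(x)) < 2) return(c(0, 1))
  kt <- stats::kruskal.test(x, rep(1:2, c(length(a), length(b))))
  c(unname(kt$statistic), kt$p.value)
}

match_z <- function(z, z_values) {
  i <- vapply(z, function(v) {
    j <- which(abs(z_values - v) < 1e-12)
    if (length(j) != 1) NA_integer_ else j
  }, 1L)
  i
}

#' Run the z-value sensitivity study
#'
#' Given per-cell summaries computed at every z of the grid (columns
#' `cell_line`, `condition`, `cell_id`, `z` and the response count), runs
#' one pairwise Kruskal-Wallis test per hypothesis-grid entry and flags
#' significance at the Bonferroni-corrected level `alpha / m`. Also
#' attaches the per-z mean count per group (the quantity plotted against
#' z in the sensitivity figures).
#'
#' @param summaries Tibble of per-cell summaries across the z grid.
#' @param config A [sweep_config()]; its `z_values`, `conditions` and
#'   `cell_lines` must all occur in `summaries`.
#' @return A tibble of class `punctaflux_sweep`, one row per hypothesis:
#'   grid columns plus `n_a`, `n_b`, `mean_a`, `mean_b`, `statistic`,
#'   `p_value`, `corrected_alpha`, `significant`. Attributes: `m`,
#'   `alpha`, `response`, `group_means` (per cell line x condition x z).
#' @export
run_sweep <- function(summaries, config = sweep_config()) {
  resp <- config$response
  stopifnot(resp %in% names(summaries))
  grid <- build_hypothesis_grid(config)
  ca <- attr(grid, "corrected_alpha")
  # index the counts once: one vector per (cell line, condition, z) group
  zi <- match_z(summaries$z, config$z_values)
  key <- paste(summaries$cell_line, summaries$condition, zi, sep = "\r")
  groups <- split(summaries[[resp]], key)
  gkey <- function(line, cond, z) {
    paste(line, cond, match_z(z, config$z_values), sep = "\r")
  }
  res <- matrix(NA_real_, nrow(grid), 6,
                dimnames = list(NULL, c("n_a", "n_b", "mean_a", "mean_b",
                                        "statistic", "p_value")))
  for (i in seq_len(nrow(grid))) {
    a <- groups[[gkey(grid$cell_line[i], grid$condition_a[i], grid$z[i])]]
    b <- groups[[gkey(grid$cell_line[i], grid$condition_b[i], grid$z[i])]]
    res[i, 1:4] <- c(length(a), length(b),
                     if (length(a)) mean(a) else NA_real_,
                     if (length(b)) mean(b) else NA_real_)
    if (length(a) && length(b)) {
      kt <- kruskal_hp(a, b)
      res[i, 5:6] <- kt
    }
  }
  out <- dplyr::bind_cols(grid, as_tibble(res)) |>
    dplyr::mutate(n_a = as.integer(.data$n_a), n_b = as.integer(.data$n_b),
                  corrected_alpha = ca,
                  significant = !is.na(.data$p_value) & .data$p_value < ca)
  group_means <- summaries |>
    dplyr::group_by(.data$cell_line, .data$condition, .data$z) |>
    dplyr::summarise(mean_count = mean(.data[[resp]]), n_cells = dplyr::n(),
                     .groups = "drop")
  attr(out, "m") <- config$m
  attr(out, "alpha") <- config$alpha
  attr(out, "response") <- resp
  attr(out, "group_means") <- group_means
  class(out) <- c("punctaflux_sweep", class(out))
  out
}

#' Per-cell summaries of a set of scenes across a z grid
#'
#' The detection half of the sensitivity study: for each scene (one cell),
#' detects GFP and mRFP puncta at every z of the grid, forms dual puncta,
#' associates them with the mitochondrial segmentation, and emits one
#' [summarize_cell()] row per (cell, z). The LoG response of each channel
#' is computed once per scene and re-thresholded at every z. Detection
#' statistics use the ground-truth cell mask of the scene when `masks` are
#' supplied, otherwise the whole frame.
#'
#' @param scenes List of `scene` objects (one cell each).
#' @param meta Tibble with one row per scene: `cell_id`, `condition`,
#'   `cell_line`.
#' @param z_values Grid of thresholds.
#' @param masks Optional list of `cell_mask` objects (or logical
#'   matrices), one per scene.
#' @param params Base [detection_params()] for the LC3 channels.
#' @param mito_params [detection_params()] for the mitochondria channel
#'   (default: same z, no area filter).
#' @param cutoff_px Association cutoff (default 5).
#' @return Tibble of per-cell summaries with a `z` column, ready for
#'   [run_sweep()].
#' @export
summarize_scenes_over_z <- function(scenes, meta, z_values,
                                    masks = NULL,
                                    params = detection_params(),
                                    mito_params = NULL,
                                    cutoff_px = 5) {
  stopifnot(length(scenes) == nrow(meta))
  rows <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    mask <- if (!is.null(masks)) {
      m <- masks[[i]]
      if (inherits(m, "cell_mask")) m$mask else m
    } else NULL
    resp <- lapply(sc$channels, log_filter, sigma_px = params$sigma_px)
    mp <- mito_params %||% detection_params(z = params$z,
                                            sigma_px = params$sigma_px,
                                            min_area_px = 0)
    for (z in z_values) {
      det <- lapply(c(gfp = "gfp", rfp = "rfp"), function(ch) {
        mk <- threshold_response(resp[[ch]], z, mask)
        obj <- label_objects(mk, sc$channels[[ch]], params$connectivity, ch)
        obj <- filter_min_area(obj, params$min_area_px,
                               params$area_filter_inclusive)
        if (!is.null(mask)) obj <- clip_to_cell(obj, mask)
        obj
      })
      mito_mask <- threshold_response(resp$mito, mp$z, mask)
      mito <- label_objects(mito_mask, sc$channels$mito, mp$connectivity,
                            "mito")
      mito <- filter_min_area(mito, mp$min_area_px,
                              mp$area_filter_inclusive)
      duals <- build_dual_puncta(det$gfp, det$rfp, dim = dim(sc$channels$gfp))
      recs <- associate_with_mito(duals, mito, cutoff_px)
      s <- summarize_cell(det$gfp, det$rfp, duals, recs,
                          cell_id = meta$cell_id[i],
                          condition = meta$condition[i],
                          cell_line = meta$cell_line[i])
      s$z <- z
      rows[[length(rows) + 1L]] <- s
    }
  }
  dplyr::bind_rows(rows)
}
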