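#' Mitochondrial-potential ratios under autophagosomes
#'
#' For each dual (GFP+mRFP) punctum, the mean mitochondrial-dye intensity
#' over the mito-positive pixels it overlaps is compared with (a) the mean
#' over the adjacent mitochondrial segment and (b) the mean over all
#' mito-segment pixels in the cell. Ratios below 1 mean the autophagosome
#' sits on mitochondria fainter (lower potential) than its segment / the
#' cell average. The adjacent segment is the one sharing the most overlap
#' pixels (ties broken by nearest centroid). Puncta overlapping no
#' mito-positive pixel yield no record; records whose segment or cell mean
#' is zero are dropped with a warning.
#'
#' @param duals Dual-puncta tibble from [build_dual_puncta()].
#' @param mito_objects Mitochondrial segment objects (pixel sets).
#' @param mito_frame Raw mitochondrial-dye intensity matrix (never the LoG
#'   response).
#' @return A tibble with one row per overlapping punctum: `dual_id`,
#'   `mito_id`, `n_overlap_px`, `overlap_mean`, `segment_mean`,
#'   `cell_mean`, `ratio_segment`, `ratio_cell`.
#' @export
compute_ratios <- function(duals, mito_objects, mito_frame) {
  empty <- tibble(dual_id = integer(0), mito_id = integer(0),
                  n_overlap_px = integer(0), overlap_mean = numeric(0),
                  segment_mean = numeric(0), cell_mean = numeric(0),
                  ratio_segment = numeric(0), ratio_cell = numeric(0))
  if (!nrow(duals) || !nrow(mito_objects)) return(empty)
  dimm <- dim(mito_frame)
  mlin <- lapply(mito_objects$pixels, pixels_linear, dim = dimm)
  seg_means <- vapply(mlin, function(l) mean(mito_frame[l]), 0)
  cell_mean <- mean(mito_frame[unique(unlist(mlin))])
  rows <- list()
  for (i in seq_len(nrow(duals))) {
    dl <- pixels_linear(duals$pixels[[i]], dimm)
    ov <- lapply(mlin, intersect, x = dl)
    n_ov <- lengths(ov)
    if (!any(n_ov > 0)) next
    best <- which(n_ov == max(n_ov))
    if (length(best) > 1) { # tie: nearest segment centroid
      cen <- c(duals$centroid_row[i], duals$centroid_col[i])
      dc <- vapply(best, function(j) {
        px <- mito_objects$pixels[[j]]
        (mean(px[, 1]) - cen[1])^2 + (mean(px[, 2]) - cen[2])^2
      }, 0)
      best <- best[which.min(dc)]
    }
    overlap_mean <- mean(mito_frame[unlist(ov[best])])
    if (seg_means[best] == 0 || cell_mean == 0) {
      warn("zero segment or cell mean intensity; ratio record dropped")
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      dual_id = duals$id[i], mito_id = mito_objects$id[best],
      n_overlap_px = n_ov[best], overlap_mean = overlap_mean,
      segment_mean = seg_means[best], cell_mean = cell_mean,
      ratio_segment = overlap_mean / seg_means[best],
      ratio_cell = overlap_mean / cell_mean)
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  c(median = q[2], q1 = q[1], q3 = q[3], whisker_low = lo, whisker_high = hi)
}

#' Per-cell boxplot summaries of potential ratios
#'
#' Pools ratio records per cell (across Z-slices and timepoints, when the
#' records come from a movie) and computes boxplot statistics (quartiles
#' by linear interpolation; whiskers at the most extreme points within
#' 1.5 IQR of the quartiles) for both ratio definitions.
#'
#' @param records Ratio records from [compute_ratios()], with an optional
#'   `cell_id` column; a single cell is assumed when absent.
#' @return A tibble of class `punctaflux_ratio_summary` with one row per
#'   cell and ratio type (`ratio_segment`, `ratio_cell`): `cell_id`,
#'   `ratio`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n`.
#' @export
summarize_ratios <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (!"cell_id" %in% names(records)) records$cell_id <- "cell_1"
  long <- tidyr::pivot_longer(
    records[, c("cell_id", "ratio_segment", "ratio_cell")],
    cols = c("ratio_segment", "ratio_cell"),
    names_to = "ratio", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$cell_id, .data$ratio) |>
    dplyr::summarise(
      stats = list(boxplot_stats(.data$value)), n = dplyr::n(),
      .groups = "drop") |>
    tidyr::unnest_wider("stats")
  class(out) <- c("punctaflux_ratio_summary", class(out))
  out
}
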