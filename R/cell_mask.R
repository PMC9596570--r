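#' Cell-segmentation parameters
#'
#' @param quantile Intensity quantile below which pixels are suppressed
#'   (default 0.90: the dimmest 90% of pixels, i.e. the background, are
#'   zeroed and the brightest 10% — the cell — survive).
#' @param median_windows Odd, increasing median-filter window sizes applied
#'   as a cascade (default 3, 5, 9).
#' @param n_dilations Number of successive dilations widening the final
#'   mask (default 4).
#' @param dilation_radius_px Disc radius of each dilation (default 2, the
#'   system precision).
#' @param consistency_min_jaccard Minimum pairwise Jaccard overlap between
#'   per-channel masks for the segmentation to be accepted (default 0.8).
#' @return A list of class `mask_params`.
#' @export
mask_params <- function(quantile = 0.90, median_windows = c(3, 5, 9),
                        n_dilations = 4, dilation_radius_px = 2,
                        consistency_min_jaccard = 0.8) {
  stopifnot(quantile > 0, quantile < 1, all(median_windows %% 2 == 1),
            !is.unsorted(median_windows), n_dilations >= 0)
  structure(list(quantile = quantile, median_windows = median_windows,
                 n_dilations = n_dilations,
                 dilation_radius_px = dilation_radius_px,
                 consistency_min_jaccard = consistency_min_jaccard),
            class = "mask_params")
}

new_cell_mask <- function(mask, source = "automatic", valid = TRUE,
                          reason = "none") {
  structure(list(mask = mask, source = source, valid = valid,
                 rejection_reason = reason), class = "cell_mask")
}

#' Segment the single cell in one channel
#'
#' Automated live-cell segmentation: pixels below the per-image intensity
#' quantile (default 90th percentile) are zeroed, a cascade of median
#' filters (windows 3, 5, 9) despeckles the survivor image, the result is
#' binarized, and the largest connected component — the sole complete
#' cell — is kept. The quantile rule makes the step invariant to affine
#' intensity rescaling.
#'
#' @param frame Numeric intensity matrix (one channel).
#' @param params A [mask_params()].
#' @return A `cell_mask` object; invalid (reason `channel_inconsistent`)
#'   when nothing survives suppression.
#' @export
segment_cell <- function(frame, params = mask_params()) {
  assert_frame(frame)
  if (stats::var(as.vector(frame)) == 0) {
    # a flat frame carries no cell/background contrast to segment
    return(new_cell_mask(matrix(FALSE, nrow(frame), ncol(frame)),
                         valid = FALSE, reason = "channel_inconsistent"))
  }
  q <- stats::quantile(frame, params$quantile, names = FALSE)
  img <- frame
  img[img < q] <- 0
  if (!any(img > 0)) {
    return(new_cell_mask(matrix(FALSE, nrow(frame), ncol(frame)),
                         valid = FALSE, reason = "channel_inconsistent"))
  }
  sc <- max(img)
  for (w in params$median_windows) {
    img <- EBImage::imageData(EBImage::medianFilter(img / sc, (w - 1) / 2)) * sc
  }
  mask <- img > 0
  if (!any(mask)) {
    return(new_cell_mask(mask, valid = FALSE, reason = "channel_inconsistent"))
  }
  lab <- label_mask(mask, 8)
  largest <- as.integer(names(which.max(table(lab$comp))))
  out <- matrix(FALSE, nrow(frame), ncol(frame))
  out[lab$idx[lab$comp == largest]] <- TRUE
  new_cell_mask(out)
}

#' Widen and close a cell mask
#'
#' Applies `n_dilations` successive dilations with a disc of
#' `dilation_radius_px` (default 4 x 2 px, twice the system precision) so
#' that objects at the cell edge are not clipped, then a morphological
#' closing with hole filling so no holes remain where a channel is weakly
#' labelled. The output always contains the input.
#'
#' @param cm A `cell_mask` (or plain logical matrix).
#' @param params A [mask_params()].
#' @return A `cell_mask`.
#' @export
refine_mask <- function(cm, params = mask_params()) {
  m <- if (inherits(cm, "cell_mask")) cm$mask else cm
  stopifnot(any(m))
  brush <- EBImage::makeBrush(2 * params$dilation_radius_px + 1, "disc")
  x <- m * 1
  for (i in seq_len(params$n_dilations)) x <- EBImage::dilate(x, brush)
  x <- EBImage::closing(x, brush)
  x <- EBImage::fillHull(x)
  out <- EBImage::imageData(x) > 0
  new_cell_mask(out, source = if (inherits(cm, "cell_mask")) cm$source
                else "automatic")
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Cross-channel mask consistency check
#'
#' The same cell must be recovered from every channel. Computes all
#' pairwise Jaccard overlaps between per-channel masks; if the minimum is
#' at least `consistency_min_jaccard` the union consensus mask is returned
#' as valid, otherwise an invalid mask with reason `channel_inconsistent`.
#'
#' @param masks List of two or more `cell_mask` objects (or logical
#'   matrices).
#' @param params A [mask_params()].
#' @return A `cell_mask`.
#' @export
check_consistency <- function(masks, params = mask_params()) {
  stopifnot(length(masks) >= 2)
  ms <- lapply(masks, function(x) if (inherits(x, "cell_mask")) x$mask else x)
  pairs <- utils::combn(length(ms), 2)
  jac <- apply(pairs, 2, function(p) jaccard(ms[[p[1]]], ms[[p[2]]]))
  consensus <- Reduce(`|`, ms)
  if (any(is.na(jac)) || min(jac) < params$consistency_min_jaccard) {
    return(new_cell_mask(consensus, valid = FALSE,
                         reason = "channel_inconsistent"))
  }
  new_cell_mask(consensus)
}

#' Reject masks touching the image border
#'
#' A cell mask touching the first or last row or column belongs to a cell
#' that is not fully in the field of view; such frames are disregarded.
#'
#' @param cm A `cell_mask` (or logical matrix).
#' @return The `cell_mask`, invalidated with reason `touches_border` when
#'   any mask pixel lies on the image border.
#' @export
check_border <- function(cm) {
  m <- if (inherits(cm, "cell_mask")) cm$mask else cm
  out <- if (inherits(cm, "cell_mask")) cm else new_cell_mask(m)
  touches <- any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) ||
    any(m[, ncol(m)])
  if (touches) {
    out$valid <- FALSE
    out$rejection_reason <- "touches_border"
  }
  out
}

#' Automatic cell mask for a scene
#'
#' The full live-cell chain: per-channel [segment_cell()] and
#' [refine_mask()], cross-channel [check_consistency()], then
#' [check_border()]. By default the two LC3 channels are used — the
#' mitochondrial dye labels a sparse tubular network rather than the whole
#' cytosol, so it is not a reliable outline channel.
#'
#' @param scene A `scene` (from [simulate_scene()] or [read_stack()]).
#' @param params A [mask_params()].
#' @param channels Channels to segment (default `c("gfp", "rfp")`).
#' @return A `cell_mask`.
#' @export
auto_cell_mask <- function(scene, params = mask_params(),
                           channels = c("gfp", "rfp")) {
  per_channel <- lapply(channels, function(ch) {
    cm <- segment_cell(scene$channels[[ch]], params)
    if (!cm$valid) return(cm)
    refine_mask(cm, params)
  })
  bad <- !vapply(per_channel, function(x) x$valid, TRUE)
  if (any(bad)) {
    return(new_cell_mask(matrix(FALSE, nrow(scene$channels[[1]]),
                                ncol(scene$channels[[1]])),
                         valid = FALSE, reason = "channel_inconsistent"))
  }
  cm <- check_consistency(per_channel, params)
  if (!cm$valid) return(cm)
  check_border(cm)
}

#' Ingest a manually drawn single-cell ROI
#'
#' Fixed-cell mode: a user-supplied binary ROI bypasses automatic
#' segmentation but is still subject to the border-rejection rule.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return A `cell_mask` with source `manual_roi`.
#' @export
manual_cell_mask <- function(mask) {
  m <- mask > 0
  check_border(new_cell_mask(m, source = "manual_roi"))
}
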