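#' Detection parameters
#'
#' Parameters for intensity-adaptive Laplacian-of-Gaussian (LoG) puncta
#' detection. The detector filters a frame with a scale-normalized LoG of
#' standard deviation `sigma_px`, thresholds the response at
#' `mean + z * sd` (computed over `support` if given, else the whole frame),
#' labels connected components, and removes small objects.
#'
#' @param z Threshold preference (default 1.75). Higher `z` raises the
#'   response threshold: fewer, higher-confidence objects (more precision,
#'   less recall); lower `z` recovers more objects at the cost of precision.
#' @param sigma_px LoG Gaussian standard deviation in pixels (default 3,
#'   matched to the ~250 nm confocal resolution at 56.6 nm pixels).
#' @param min_area_px Minimum retained object area. Fixed-cell analysis uses
#'   25 (objects of 25 px or less are sub-resolution artifacts); live-cell
#'   autotuned analysis uses 4.
#' @param connectivity Pixel connectivity for object labeling, 4 or 8.
#' @param support Optional logical matrix restricting the threshold
#'   statistics (typically the cell mask), or `NULL` for the whole frame.
#' @param area_filter_inclusive If `TRUE` (default) objects with
#'   `area_px <= min_area_px` are removed; if `FALSE` only strictly smaller
#'   objects are removed.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(z = 1.75, sigma_px = 3, min_area_px = 25,
                             connectivity = 8, support = NULL,
                             area_filter_inclusive = TRUE) {
  stopifnot(z > 0, sigma_px >= 1, min_area_px >= 0,
            connectivity %in% c(4, 8))
  structure(list(z = z, sigma_px = sigma_px, min_area_px = min_area_px,
                 connectivity = connectivity, support = support,
                 area_filter_inclusive = area_filter_inclusive),
            class = "detection_params")
}

log_kernel <- function(sigma) {
  radius <- ceiling(4 * sigma)
  ax <- (-radius):radius
  x2 <- outer(ax^2, rep(1, length(ax)))
  r2 <- x2 + t(x2)
  # negated, scale-normalized LoG: bright blobs -> positive peaks
  k <- (2 * sigma^2 - r2) / (2 * pi * sigma^4) * exp(-r2 / (2 * sigma^2))
  k - mean(k) # exact zero response on constant input
}

#' Scale-normalized LoG filter
#'
#' Filters a frame with a negated, scale-normalized (multiplied by
#' \eqn{\sigma^2}) Laplacian-of-Gaussian, so bright blobs of scale
#' `sigma_px` produce positive response peaks. Boundaries are handled by
#' reflection. A constant frame gives an identically zero response.
#'
#' @param frame Numeric matrix of intensities.
#' @param sigma_px Gaussian standard deviation of the LoG, in pixels.
#' @return Numeric matrix of responses, same shape as `frame`.
#' @export
log_filter <- function(frame, sigma_px = 3) {
  assert_frame(frame)
  stopifnot(sigma_px >= 1)
  convolve_reflect(frame, log_kernel(sigma_px))
}

#' Threshold a response map adaptively
#'
#' Binarizes an LoG response at `mean + z * sd`, with the mean and standard
#' deviation taken over `support` (e.g. the cell mask) or the whole frame.
#' The mask is pixelwise monotone non-increasing in `z`. A zero-variance
#' response yields an empty mask with a warning.
#'
#' @param response Response matrix from [log_filter()].
#' @param z Threshold preference, `> 0`.
#' @param support Optional logical matrix; statistics are computed over its
#'   `TRUE` pixels only.
#' @return Logical matrix.
#' @export
threshold_response <- function(response, z, support = NULL) {
  assert_frame(response, "response")
  stopifnot(z > 0)
  vals <- if (is.null(support)) as.vector(response) else {
    stopifnot(is.logical(support), any(support))
    response[support]
  }
  mu <- mean(vals)
  sd_ <- stats::sd(vals)
  if (!is.finite(sd_) || sd_ == 0) {
    warn("zero response variance; returning empty mask")
    return(matrix(FALSE, nrow(response), ncol(response)))
  }
  response > mu + z * sd_
}

# Connected components of a logical mask via a pixel-adjacency graph.
label_mask <- function(mask, connectivity = 8) {
  idx <- which(mask)
  n <- nrow(mask)
  if (!length(idx)) return(list(idx = idx, comp = integer(0)))
  pos <- match(idx, idx)
  lut <- integer(length(mask)); lut[idx] <- seq_along(idx)
  row <- (idx - 1L) %% n + 1L
  offs <- list(c(1L, 0L), c(0L, 1L)) # down, right
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  for (o in offs) {
    nb <- idx + o[1] + o[2] * n
    nbrow <- row + o[1]
    ok <- nbrow >= 1L & nbrow <= n & nb >= 1L & nb <= length(mask)
    ok[ok] <- mask[nb[ok]]
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(lut[idx[ok]], lut[nb[ok]])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(idx)]
  list(idx = idx, comp = comp)
}

#' Label connected components of a binary mask as puncta objects
#'
#' Forms one object per connected component of `mask`; object intensities
#' are sampled from the originating `frame` (never from the response map).
#'
#' @param mask Logical matrix of detected pixels.
#' @param frame Numeric matrix the mask was derived from.
#' @param connectivity 4 or 8 (default 8).
#' @param channel Optional channel label stored with each object.
#' @return A tibble with one row per object: `id`, `channel`, `area_px`,
#'   `centroid_row`, `centroid_col`, `mean_intensity`, `max_intensity`, and
#'   list-columns `pixels` (integer matrix of row/col) and `intensities`.
#' @export
label_objects <- function(mask, frame, connectivity = 8, channel = NA_character_) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(frame)))
  lab <- label_mask(mask, connectivity)
  if (!length(lab$idx)) return(empty_objects(channel))
  n <- nrow(mask)
  row <- (lab$idx - 1L) %% n + 1L
  col <- (lab$idx - 1L) %/% n + 1L
  ints <- frame[lab$idx]
  ord <- order(lab$comp)
  comp <- lab$comp[ord]; row <- row[ord]; col <- col[ord]; ints <- ints[ord]
  split_idx <- unname(split(seq_along(comp), comp))
  tibble(
    id = seq_along(split_idx),
    channel = channel,
    area_px = lengths(split_idx),
    centroid_row = vapply(split_idx, function(i) mean(row[i]), 0),
    centroid_col = vapply(split_idx, function(i) mean(col[i]), 0),
    mean_intensity = vapply(split_idx, function(i) mean(ints[i]), 0),
    max_intensity = vapply(split_idx, function(i) max(ints[i]), 0),
    pixels = lapply(split_idx, function(i) cbind(row = row[i], col = col[i])),
    intensities = lapply(split_idx, function(i) ints[i])
  )
}

empty_objects <- function(channel = NA_character_) {
  tibble(id = integer(0), channel = character(0), area_px = integer(0),
         centroid_row = numeric(0), centroid_col = numeric(0),
         mean_intensity = numeric(0), max_intensity = numeric(0),
         pixels = list(), intensities = list())
}

#' Remove small objects
#'
#' Removes objects at or below `min_area_px` (inclusive by default: an
#' object of exactly `min_area_px` pixels is removed, matching the
#' "`min_area_px` pixels or less" sub-resolution rule).
#'
#' @param objects Object tibble from [label_objects()].
#' @param min_area_px Area threshold in pixels.
#' @param inclusive Remove `area_px <= min_area_px` (default) rather than
#'   `area_px < min_area_px`.
#' @return Filtered object tibble.
#' @export
filter_min_area <- function(objects, min_area_px, inclusive = TRUE) {
  keep <- if (inclusive) objects$area_px > min_area_px
          else objects$area_px >= min_area_px
  objects[keep, , drop = FALSE]
}

#' Detect puncta in one channel
#'
#' The full detection chain: [log_filter()], [threshold_response()],
#' [label_objects()], [filter_min_area()].
#'
#' @param frame Numeric intensity matrix.
#' @param params A [detection_params()] object.
#' @param channel Optional channel label.
#' @return Object tibble (see [label_objects()]).
#' @export
detect_puncta <- function(frame, params = detection_params(),
                          channel = NA_character_) {
  resp <- log_filter(frame, params$sigma_px)
  mask <- threshold_response(resp, params$z, params$support)
  obj <- label_objects(mask, frame, params$connectivity, channel)
  filter_min_area(obj, params$min_area_px, params$area_filter_inclusive)
}

#' High-recall autotuned detection for live-cell mode
#'
#' Runs [detect_puncta()] at a lowered threshold `z = z_base / ratio`
#' (default base 1.75, ratio 3.75), deliberately over-detecting; the result
#' is meant to be pruned by the [apply_qc()] false-positive filters. The
#' live-mode minimum area (4 px) is applied.
#'
#' @param frame Numeric intensity matrix.
#' @param ratio Recall/precision preference ratio, `> 0`; 1 reproduces the
#'   default detection, larger values lower the threshold.
#' @param params Base [detection_params()]; its `z` is divided by `ratio`
#'   and its `min_area_px` replaced by the live-mode value 4.
#' @param channel Optional channel label.
#' @return Object tibble.
#' @export
autotune_detect <- function(frame, ratio = 3.75, params = detection_params(),
                            channel = NA_character_) {
  stopifnot(ratio > 0)
  p <- params
  p$z <- params$z / ratio
  p$min_area_px <- 4
  detect_puncta(frame, p, channel)
}
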