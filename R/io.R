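#' Write a scene or movie as multi-page TIFF
#'
#' Pages are written in channel-fastest order (channel, then Z, then
#' timepoint), as 16-bit grayscale; intensities are stored as integer
#' counts in \[0, 65535\], so integer-valued images round-trip exactly. A
#' JSON sidecar (`<path>.json`) records the dimension order, channel
#' names, pixel size and page layout.
#'
#' @param x A `scene`, or a movie as returned by [simulate_timelapse()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "scene")) {
    pages <- x$channels
    meta <- list(dimension_order = "C", channels = names(x$channels),
                 n_z = 1L, n_t = 1L, pixel_size_nm = x$pixel_size_nm)
  } else if (is.list(x) && !is.null(x$frames)) {
    chn <- names(x$frames[[1]][[1]]$channels)
    pages <- list()
    for (t in seq_along(x$frames)) {
      for (z in seq_along(x$frames[[t]])) {
        for (ch in chn) {
          pages[[length(pages) + 1L]] <- x$frames[[t]][[z]]$channels[[ch]]
        }
      }
    }
    meta <- list(dimension_order = "CZT", channels = chn,
                 n_z = length(x$frames[[1]]), n_t = length(x$frames),
                 pixel_size_nm = x$frames[[1]][[1]]$pixel_size_nm,
                 z_spacing_nm = x$z_spacing_nm %||% NA)
  } else {
    abort("`x` must be a scene or a simulated movie")
  }
  tiff::writeTIFF(lapply(pages, function(p) pmin(pmax(p, 0), 65535) / 65535),
                  path, bits.per.sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-channel TIFF stack
#'
#' Reads a multi-page TIFF written by [write_stack()] (or any stack whose
#' page layout is declared through `channels`, `n_z`, `n_t`). Returns a
#' single `scene` when the stack has one timepoint and one Z-slice, else a
#' nested list of scenes indexed `[[t]][[z]]`.
#'
#' @param path TIFF path; `<path>.json` sidecar metadata is used when
#'   present.
#' @param channels Channel names, in page order (overrides the sidecar).
#' @param n_z,n_t Z-slices and timepoints (override the sidecar).
#' @param pixel_size_nm Pixel size when no sidecar is present
#'   (default 56.6).
#' @return A `scene` or a list-of-lists of scenes.
#' @export
read_stack <- function(path, channels = NULL, n_z = NULL, n_t = NULL,
                       pixel_size_nm = 56.6) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  channels <- channels %||% meta$channels
  n_z <- n_z %||% meta$n_z %||% 1L
  n_t <- n_t %||% meta$n_t %||% 1L
  pixel_size_nm <- meta$pixel_size_nm %||% pixel_size_nm
  if (is.null(channels)) abort("channel names required (no sidecar found)")
  pages <- tiff::readTIFF(path, all = TRUE)
  expected <- length(channels) * n_z * n_t
  if (length(pages) != expected) {
    abort(sprintf(
      "stack %s has %d pages but %d channels x %d Z x %d T = %d declared",
      path, length(pages), length(channels), n_z, n_t, expected))
  }
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1) abort("inconsistent frame shapes in stack")
  pages <- lapply(pages, function(p) round(p * 65535))
  k <- 0L
  movie <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    movie[[t]] <- vector("list", n_z)
    for (z in seq_len(n_z)) {
      chs <- stats::setNames(pages[k + seq_along(channels)], channels)
      k <- k + length(channels)
      movie[[t]][[z]] <- structure(
        list(channels = chs, pixel_size_nm = pixel_size_nm,
             image_size = dim(chs[[1]])), class = "scene")
    }
  }
  if (n_t == 1L && n_z == 1L) movie[[1]][[1]] else movie
}

#' Write a label-map TIFF and per-object CSV for a detection
#'
#' The label map is a 16-bit TIFF in which each object's pixels carry its
#' id; the CSV holds one row per object (id, channel, area, centroid,
#' intensity summaries).
#'
#' @param objects Object tibble from [detect_puncta()].
#' @param dim Image dimensions.
#' @param tiff_path,csv_path Output paths (either may be `NULL` to skip).
#' @return The object table without list-columns, invisibly.
#' @export
write_objects <- function(objects, dim, tiff_path = NULL, csv_path = NULL) {
  if (!is.null(tiff_path)) {
    lab <- matrix(0, dim[1], dim[2])
    for (i in seq_len(nrow(objects))) {
      px <- objects$pixels[[i]]
      lab[cbind(px[, 1], px[, 2])] <- objects$id[i]
    }
    tiff::writeTIFF(lab / 65535, tiff_path, bits.per.sample = 16L)
  }
  flat <- objects[, setdiff(names(objects), c("pixels", "intensities",
                                              "gfp_ids", "rfp_ids"))]
  if (!is.null(csv_path)) readr::write_csv(flat, csv_path)
  invisible(flat)
}

#' Rebuild an object table from a label map
#'
#' Inverse of the label-map output of [write_objects()]: every nonzero
#' label value becomes one object, with intensities sampled from `frame`.
#'
#' @param label Integer label matrix (ids, 0 = background).
#' @param frame Intensity matrix.
#' @param channel Optional channel label.
#' @return Object tibble.
#' @export
objects_from_label_map <- function(label, frame, channel = NA_character_) {
  ids <- sort(unique(label[label > 0]))
  rows <- lapply(seq_along(ids), function(k) {
    px <- which(label == ids[k], arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    ints <- frame[px]
    tibble(id = k, channel = channel, area_px = nrow(px),
           centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
           mean_intensity = mean(ints), max_intensity = max(ints),
           pixels = list(px), intensities = list(ints))
  })
  if (!length(rows)) return(empty_objects(channel)) else dplyr::bind_rows(rows)
}
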