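#' Dual-channel (GFP + mRFP) puncta
#'
#' A GFP and an mRFP object sharing at least one pixel mark the same
#' neutral-pH autophagosome; the union of the overlapping puncta is
#' counted as one dual punctum. One-to-many overlaps are resolved as the
#' connected components of the bipartite GFP/mRFP overlap graph: every
#' component containing at least one cross-channel edge becomes one dual
#' punctum whose pixel set is the union over its members.
#'
#' @param gfp_objects,rfp_objects Object tibbles from [detect_puncta()],
#'   detected in the same frame and cell.
#' @param dim Image dimensions (rows, cols) used to index pixels; taken
#'   from the largest coordinate when omitted.
#' @return A tibble with one row per dual punctum: `id`, list-columns
#'   `gfp_ids`, `rfp_ids`, `pixels`, plus `area_px`, `centroid_row`,
#'   `centroid_col`.
#' @export
build_dual_puncta <- function(gfp_objects, rfp_objects, dim = NULL) {
  empty <- tibble(id = integer(0), gfp_ids = list(), rfp_ids = list(),
                  pixels = list(), area_px = integer(0),
                  centroid_row = numeric(0), centroid_col = numeric(0))
  if (!nrow(gfp_objects) || !nrow(rfp_objects)) return(empty)
  if (is.null(dim)) {
    allpx <- rbind(do.call(rbind, gfp_objects$pixels),
                   do.call(rbind, rfp_objects$pixels))
    dim <- c(max(allpx[, 1]), max(allpx[, 2]))
  }
  glin <- lapply(gfp_objects$pixels, pixels_linear, dim = dim)
  rlin <- lapply(rfp_objects$pixels, pixels_linear, dim = dim)
  ng <- length(glin)
  edges <- list()
  for (i in seq_len(ng)) {
    for (j in seq_along(rlin)) {
      if (length(intersect(glin[[i]], rlin[[j]]))) {
        edges[[length(edges) + 1L]] <- c(i, ng + j)
      }
    }
  }
  if (!length(edges)) return(empty)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, ng + length(rlin) - igraph::vcount(g)))
  comp <- igraph::components(g)
  comps <- split(seq_len(ng + length(rlin)), comp$membership)
  comps <- Filter(function(v) any(v <= ng) && any(v > ng), comps)
  rows <- lapply(seq_along(comps), function(k) {
    v <- comps[[k]]
    gids <- v[v <= ng]
    rids <- v[v > ng] - ng
    lin <- unique(c(unlist(glin[gids]), unlist(rlin[rids])))
    px <- cbind(row = (lin - 1L) %% dim[1] + 1L,
                col = (lin - 1L) %/% dim[1] + 1L)
    tibble(id = k, gfp_ids = list(gfp_objects$id[gids]),
           rfp_ids = list(rfp_objects$id[rids]), pixels = list(px),
           area_px = nrow(px), centroid_row = mean(px[, 1]),
           centroid_col = mean(px[, 2]))
  })
  dplyr::bind_rows(rows)
}

#' Minimum edge-to-edge distance between two pixel sets
#'
#' Euclidean distance between the closest pixels of two objects, in
#' pixels; 0 when the sets share a pixel.
#'
#' @param pixels_a,pixels_b Pixel-set matrices (columns row, col).
#' @return A single non-negative number.
#' @export
min_edge_distance <- function(pixels_a, pixels_b) {
  if (!NROW(pixels_a) || !NROW(pixels_b)) abort("empty pixel set")
  # chunk the cross-distance computation to bound memory on large objects
  best <- Inf
  step <- max(1L, floor(4e6 / NROW(pixels_b)))
  for (s in seq(1L, NROW(pixels_a), by = step)) {
    ai <- pixels_a[s:min(NROW(pixels_a), s + step - 1L), , drop = FALSE]
    d2 <- outer(ai[, 1], pixels_b[, 1], `-`)^2 +
      outer(ai[, 2], pixels_b[, 2], `-`)^2
    best <- min(best, min(d2))
    if (best == 0) break
  }
  sqrt(best)
}

#' Associate dual puncta with mitochondria
#'
#' Puncta within `cutoff_px` (default 5 px, the ceil of the system
#' precision, i.e. the ~250 nm resolution limit) of a mitochondrial
#' segment cannot be distinguished from overlapping ones and are counted
#' as associated. Distances are nearest-edge Euclidean distances.
#'
#' @param duals Dual-puncta tibble from [build_dual_puncta()].
#' @param mito_objects Mitochondrial segments (object tibble, typically
#'   [detect_puncta()] on the mitochondria channel with `min_area_px = 0`).
#' @param cutoff_px Association cutoff, inclusive (default 5).
#' @return A tibble with one row per dual punctum: `dual_id`,
#'   `nearest_mito_id`, `edge_distance_px`, `associated`.
#' @export
associate_with_mito <- function(duals, mito_objects, cutoff_px = 5) {
  if (!nrow(duals)) {
    return(tibble(dual_id = integer(0), nearest_mito_id = integer(0),
                  edge_distance_px = numeric(0), associated = logical(0)))
  }
  if (!nrow(mito_objects)) {
    return(tibble(dual_id = duals$id, nearest_mito_id = NA_integer_,
                  edge_distance_px = NA_real_, associated = FALSE))
  }
  recs <- lapply(seq_len(nrow(duals)), function(i) {
    d <- vapply(mito_objects$pixels, min_edge_distance,
                0, pixels_a = duals$pixels[[i]])
    j <- which.min(d)
    tibble(dual_id = duals$id[i], nearest_mito_id = mito_objects$id[j],
           edge_distance_px = d[j], associated = d[j] <= cutoff_px)
  })
  dplyr::bind_rows(recs)
}

#' Restrict objects to a cell
#'
#' Keeps objects with at least half of their pixels inside the cell mask;
#' the mask is dilated upstream precisely so that genuine objects at the
#' cell edge are not clipped.
#'
#' @param objects Object or dual-puncta tibble with a `pixels`
#'   list-column.
#' @param cell_mask A `cell_mask` or logical matrix.
#' @param min_frac Minimum fraction of pixels inside (default 0.5).
#' @return Filtered tibble.
#' @export
clip_to_cell <- function(objects, cell_mask, min_frac = 0.5) {
  m <- if (inherits(cell_mask, "cell_mask")) cell_mask$mask else cell_mask
  if (!nrow(objects)) return(objects)
  frac <- vapply(objects$pixels, function(px) {
    mean(m[cbind(px[, 1], px[, 2])])
  }, 0)
  objects[frac >= min_frac, , drop = FALSE]
}

#' Per-cell puncta summary
#'
#' Counts detected objects per channel, dual puncta, and dual puncta
#' associated with mitochondria, for one valid cell.
#'
#' @param gfp_objects,rfp_objects Channel object tibbles (already
#'   restricted to the cell).
#' @param duals Dual puncta from [build_dual_puncta()].
#' @param records Association records from [associate_with_mito()].
#' @param cell_id,condition,cell_line,timepoint Metadata carried into the
#'   summary.
#' @return One-row tibble: `cell_id`, `condition`, `cell_line`,
#'   `timepoint`, `n_gfp`, `n_rfp`, `n_dual`, `n_dual_near_mito`,
#'   `fraction_near_mito` (`NA` when `n_dual` is 0).
#' @export
summarize_cell <- function(gfp_objects, rfp_objects, duals, records,
                           cell_id = NA_character_,
                           condition = NA_character_,
                           cell_line = NA_character_, timepoint = NA_real_) {
  n_dual <- nrow(duals)
  n_near <- if (nrow(records)) sum(records$associated) else 0L
  tibble(cell_id = cell_id, condition = condition, cell_line = cell_line,
         timepoint = timepoint,
         n_gfp = nrow(gfp_objects), n_rfp = nrow(rfp_objects),
         n_dual = n_dual, n_dual_near_mito = n_near,
         fraction_near_mito = if (n_dual > 0) n_near / n_dual else NA_real_)
}
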