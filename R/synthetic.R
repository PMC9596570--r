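#' Specification of a synthetic tfLC3 scene
#'
#' Describes one ground-truthed synthetic confocal field: a single
#' elliptical cell with diffuse cytosolic LC3 fluorescence in the GFP and
#' mRFP channels, Gaussian-profile puncta (GFP-only, mRFP-only, and
#' spatially coincident dual puncta), a tubular mitochondrial network whose
#' per-segment intensity encodes membrane potential, and Poisson + Gaussian
#' camera noise. The rendered images are integer-valued (camera counts).
#'
#' @param image_size Height and width in pixels.
#' @param pixel_size_nm Pixel size (default 56.6 nm).
#' @param cell_center,cell_axes,cell_theta Ellipse center (row, col),
#'   semi-axes (pixels) and orientation (radians). Defaults place a cell
#'   covering roughly 11% of the field, so that the 90%-quantile automated
#'   segmentation is meaningful.
#' @param edge_sigma_px Softness of the cytosol edge (Gaussian blur of the
#'   cell profile, pixels). Real confocal cell margins fall off over a few
#'   hundred nm; a hard step would be an unrealistic LoG edge artifact.
#' @param cytosol_level Named list of in-cell diffuse levels per channel
#'   (`gfp`, `rfp`, `mito`).
#' @param background_level Extracellular background level (all channels).
#' @param n_gfp_only,n_rfp_only,n_dual Puncta counts per class.
#' @param puncta_sigma_px Gaussian spot standard deviation (default 3).
#' @param puncta_peak_snr Peak amplitude divided by the cytosol noise SD.
#' @param frac_near_mito Fraction of dual puncta placed on a mitochondrial
#'   segment (edge distance 0); the rest are placed beyond the association
#'   cutoff by a safety margin.
#' @param mito_n_segments,mito_width_px Number and thickness of tubules.
#' @param mito_base Intensity of a segment at potential multiplier 1.
#' @param mito_potential_range Range (low, high) of per-segment potential
#'   multipliers, sampled uniformly, in (0, 1].
#' @param mito_potentials Optional explicit vector of multipliers (length
#'   `mito_n_segments`), overriding `mito_potential_range`.
#' @param near_mito_segments Optional segment indices eligible for
#'   "near mito" dual-puncta placement (default: all segments); used to
#'   stratify placement by potential.
#' @param noise_gain Poisson gain (counts per photon); 0 disables shot
#'   noise.
#' @param read_noise_sd Gaussian read-noise SD in counts; 0 disables.
#' @param assoc_cutoff_px Association cutoff used for ground-truth
#'   "near mito" placement and labels (same metric as
#'   [associate_with_mito()], default 5).
#' @param min_separation_px Minimum distance between puncta centers.
#' @param seed RNG seed; the seed fully determines the output.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(400, 400), pixel_size_nm = 56.6,
                       cell_center = image_size / 2,
                       cell_axes = round(c(0.215, 0.165) * min(image_size)),
                       cell_theta = 0.35, edge_sigma_px = 6,
                       cytosol_level = list(gfp = 100, rfp = 100, mito = 30),
                       background_level = 20,
                       n_gfp_only = 5, n_rfp_only = 5, n_dual = 10,
                       puncta_sigma_px = 3, puncta_peak_snr = 8,
                       frac_near_mito = 0.5,
                       mito_n_segments = 5, mito_width_px = 3,
                       mito_base = 150, mito_potential_range = c(0.5, 1),
                       mito_potentials = NULL, near_mito_segments = NULL,
                       noise_gain = 2, read_noise_sd = 2,
                       assoc_cutoff_px = 5, min_separation_px = 12,
                       seed = 1L) {
  stopifnot(n_gfp_only >= 0, n_rfp_only >= 0, n_dual >= 0,
            frac_near_mito >= 0, frac_near_mito <= 1,
            puncta_sigma_px >= 1, mito_n_segments >= 0,
            all(mito_potential_range > 0), all(mito_potential_range <= 1),
            noise_gain >= 0, read_noise_sd >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

#' Specification of a synthetic time-lapse movie
#'
#' Extends a [scene_spec()] with timepoints, Z-slices (independently
#' rendered 2-D scenes sharing the frame's geometry) and rigid cell drift.
#' Defaults mirror spinning-disk acquisition of 7 Z-slices at 500 nm
#' spacing.
#'
#' @param scene A [scene_spec()].
#' @param n_timepoints Number of timepoints.
#' @param n_zslices Z-slices per timepoint (default 7).
#' @param z_spacing_nm Z spacing (default 500 nm, metadata only).
#' @param drift_px_per_frame Length-2 (row, col) translation of the whole
#'   cell per timepoint.
#' @param puncta_motion_px SD of per-timepoint Gaussian jitter applied to
#'   each punctum center.
#' @return A list of class `timelapse_spec`.
#' @export
timelapse_spec <- function(scene = scene_spec(), n_timepoints = 5,
                           n_zslices = 7, z_spacing_nm = 500,
                           drift_px_per_frame = c(0, 0),
                           puncta_motion_px = 0) {
  stopifnot(inherits(scene, "scene_spec"), n_timepoints >= 1, n_zslices >= 1)
  structure(list(scene = scene, n_timepoints = n_timepoints,
                 n_zslices = n_zslices, z_spacing_nm = z_spacing_nm,
                 drift_px_per_frame = drift_px_per_frame,
                 puncta_motion_px = puncta_motion_px),
            class = "timelapse_spec")
}

cytosol_noise_sd <- function(spec, channel = "gfp") {
  v <- spec$noise_gain * spec$cytosol_level[[channel]] + spec$read_noise_sd^2
  if (v <= 0) 1 else sqrt(v)
}

# Random-walk tubule rasterized to a pixel set, dilated to mito_width_px.
draw_tubule <- function(start, dim, width, n_steps = 35, step = 1.3,
                        inside) {
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n_steps + 1, 2)
  pts[1, ] <- start
  p <- start
  for (i in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, 0.35)
    cand <- p + step * c(cos(theta), sin(theta))
    if (!inside(cand)) { theta <- theta + pi; cand <- p + step * c(cos(theta), sin(theta)) }
    if (!inside(cand)) break
    p <- cand
    pts[i + 1, ] <- p
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  rad <- max(0.5, width / 2)
  px <- unique(do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    disc_pixels(pts[i, ], rad, dim)
  })))
  px
}

place_mito <- function(spec, cell) {
  dim <- spec$image_size
  inner <- function(p) {
    dr <- p[1] - cell$center[1]; dc <- p[2] - cell$center[2]
    u <- dr * cos(cell$theta) + dc * sin(cell$theta)
    v <- -dr * sin(cell$theta) + dc * cos(cell$theta)
    (u / (cell$axes[1] - 4))^2 + (v / (cell$axes[2] - 4))^2 <= 1
  }
  if (spec$mito_n_segments == 0) {
    return(tibble(id = integer(0), potential = numeric(0), pixels = list()))
  }
  pots <- spec$mito_potentials %||%
    stats::runif(spec$mito_n_segments, spec$mito_potential_range[1],
                 spec$mito_potential_range[2])
  stopifnot(length(pots) == spec$mito_n_segments)
  segs <- list()
  occupied <- matrix(FALSE, dim[1], dim[2])
  guard <- EBImage::makeBrush(5, "disc") # 2-px clearance between segments
  for (i in seq_len(spec$mito_n_segments)) {
    for (try in 1:200) {
      repeat {
        s <- c(stats::runif(1, 1, dim[1]), stats::runif(1, 1, dim[2]))
        if (inner(s)) break
      }
      px <- draw_tubule(s, dim, spec$mito_width_px, inside = inner)
      if (nrow(px) < 5 * spec$mito_width_px) next
      if (!any(occupied[px])) break
      if (try == 200) abort("could not place disjoint mitochondrial segments")
    }
    m <- pixels_to_mask(px, dim)
    occupied <- occupied |
      EBImage::imageData(EBImage::dilate(m * 1, guard)) > 0
    segs[[i]] <- px
  }
  tibble(id = seq_along(segs), potential = pots, pixels = segs)
}

place_puncta <- function(spec, cell, mito) {
  dim <- spec$image_size
  sig <- spec$puncta_sigma_px
  margin <- 4 * sig + 2
  n_total <- spec$n_gfp_only + spec$n_rfp_only + spec$n_dual
  if (n_total == 0) {
    return(tibble(id = integer(0), channel = character(0), row = numeric(0),
                  col = numeric(0), sigma = numeric(0), amplitude = numeric(0),
                  near_mito = logical(0)))
  }
  inner <- function(p) {
    dr <- p[1] - cell$center[1]; dc <- p[2] - cell$center[2]
    u <- dr * cos(cell$theta) + dc * sin(cell$theta)
    v <- -dr * sin(cell$theta) + dc * cos(cell$theta)
    a <- max(cell$axes[1] - margin, 2); b <- max(cell$axes[2] - margin, 2)
    (u / a)^2 + (v / b)^2 <= 1
  }
  mito_px <- if (nrow(mito)) do.call(rbind, mito$pixels) else NULL
  near_idx <- spec$near_mito_segments %||% seq_len(nrow(mito))
  near_px <- if (nrow(mito)) do.call(rbind, mito$pixels[near_idx]) else NULL
  dist_to_mito <- function(p) {
    if (is.null(mito_px)) Inf
    else sqrt(min((mito_px[, 1] - p[1])^2 + (mito_px[, 2] - p[2])^2))
  }
  # ground-truth footprint radius of a punctum (see truth_radius())
  r_truth <- truth_radius(sig)
  far_min <- spec$assoc_cutoff_px + r_truth + 4 # margin keeps the label robust
  n_near <- round(spec$frac_near_mito * spec$n_dual)
  if (n_near > 0 && is.null(mito_px)) {
    abort("frac_near_mito > 0 requires mitochondrial segments")
  }
  # place the distance-constrained far duals first, then near duals (easy:
  # on a segment), then the unconstrained single-channel puncta
  classes <- c(rep("dual_far", spec$n_dual - n_near),
               rep("dual_near", n_near),
               rep("gfp", spec$n_gfp_only), rep("rfp", spec$n_rfp_only))
  centers <- place_puncta_centers(spec, classes, inner, dim, near_px,
                                  dist_to_mito, far_min)
  snr_sd <- cytosol_noise_sd(spec, "gfp")
  tibble(
    id = seq_along(classes),
    channel = ifelse(classes %in% c("dual_near", "dual_far"), "dual",
                     classes),
    row = centers[, 1], col = centers[, 2],
    sigma = sig, amplitude = spec$puncta_peak_snr * snr_sd,
    near_mito = ifelse(classes == "dual_near", TRUE,
                       ifelse(classes == "dual_far", FALSE, NA))
  )
}

# Sequential dart throwing with whole-configuration restarts: an unlucky
# early placement can strand a later constrained one, so on exhaustion the
# full configuration is redrawn before giving up.
place_puncta_centers <- function(spec, classes, inner, dim, near_px,
                                 dist_to_mito, far_min, restarts = 10) {
  for (attempt in seq_len(restarts)) {
    centers <- try_place_once(spec, classes, inner, dim, near_px,
                              dist_to_mito, far_min)
    if (!is.null(centers)) return(centers)
  }
  abort("puncta placement infeasible for cell area (retry budget exhausted)")
}

try_place_once <- function(spec, classes, inner, dim, near_px,
                           dist_to_mito, far_min) {
  centers <- matrix(NA_real_, length(classes), 2)
  placed <- 0L
  for (k in seq_along(classes)) {
    ok <- FALSE
    for (try in 1:2000) {
      p <- if (classes[k] == "dual_near") {
        j <- sample.int(nrow(near_px), 1)
        as.numeric(near_px[j, ]) + stats::runif(2, -1, 1)
      } else {
        c(stats::runif(1, 1, dim[1]), stats::runif(1, 1, dim[2]))
      }
      if (!inner(p)) next
      # only dual puncta need an unambiguous near/far ground-truth label;
      # single-channel puncta may fall anywhere in the cell
      if (classes[k] == "dual_far" && dist_to_mito(p) <= far_min) next
      if (classes[k] == "dual_near" && dist_to_mito(p) > 1.5) next
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - p[1])^2 +
              (centers[seq_len(placed), 2] - p[2])^2
        if (min(d2) < spec$min_separation_px^2) next
      }
      ok <- TRUE; break
    }
    if (!ok) return(NULL)
    placed <- placed + 1L
    centers[k, ] <- p
  }
  centers
}

# Radius of the ground-truth pixel footprint of a punctum: where the
# Gaussian falls to ~1/8 peak, close to the detector's mask extent.
truth_radius <- function(sigma) 2 * sigma

truth_pixels <- function(p, dim) {
  disc_pixels(c(p$row, p$col), truth_radius(p$sigma), dim)
}

render_punctum <- function(img, row, col, sigma, amplitude) {
  rad <- ceiling(4 * sigma)
  r0 <- max(1, floor(row - rad)):min(nrow(img), ceiling(row + rad))
  c0 <- max(1, floor(col - rad)):min(ncol(img), ceiling(col + rad))
  dr <- outer(r0 - row, rep(1, length(c0)))
  dc <- outer(rep(1, length(r0)), c0 - col)
  r2 <- dr^2 + dc^2
  g <- amplitude * exp(-r2 / (2 * sigma^2))
  g[r2 > (4 * sigma)^2] <- 0 # truncate at 4 sigma
  img[r0, c0] <- img[r0, c0] + g
  img
}

apply_camera_noise <- function(img, gain, read_sd) {
  d <- dim(img)
  if (gain > 0) img <- gain * stats::rpois(length(img), img / gain)
  if (read_sd > 0) img <- img + stats::rnorm(length(img), 0, read_sd)
  matrix(pmin(pmax(round(img), 0), 65535), d[1], d[2])
}

#' Simulate one ground-truthed scene
#'
#' Renders GFP, mRFP and mitochondria channels for a [scene_spec()] and
#' returns the scene together with its ground truth. Dual puncta are
#' rendered at identical coordinates in both LC3 channels; each
#' mitochondrial segment is drawn at `mito_base * potential`; camera noise
#' is applied last. The same spec and seed always give bit-identical
#' output.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `scene` (class `scene`: `channels` list of
#'   matrices `gfp`, `rfp`, `mito`, plus `pixel_size_nm`) and `truth`
#'   (class `scene_truth`: `puncta` tibble, `mito` tibble, `cell_mask`,
#'   `expected` counts `n_dual` and `n_dual_near_mito`).
#' @export
simulate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, simulate_scene_impl(spec))
}

simulate_scene_impl <- function(spec, cell_center = NULL, puncta = NULL,
                                mito = NULL) {
  dim <- spec$image_size
  cell <- list(center = cell_center %||% spec$cell_center,
               axes = spec$cell_axes, theta = spec$cell_theta)
  cell_mask <- ellipse_mask(dim, cell$center, cell$axes, cell$theta)
  profile <- gaussian_blur(cell_mask * 1, spec$edge_sigma_px)
  if (is.null(mito)) mito <- place_mito(spec, cell)
  if (is.null(puncta)) puncta <- place_puncta(spec, cell, mito)

  channels <- list()
  for (ch in c("gfp", "rfp", "mito")) {
    img <- spec$background_level +
      (spec$cytosol_level[[ch]] - spec$background_level) * profile
    channels[[ch]] <- img
  }
  if (nrow(mito)) {
    for (i in seq_len(nrow(mito))) {
      px <- mito$pixels[[i]]
      channels$mito[cbind(px[, 1], px[, 2])] <-
        spec$cytosol_level$mito + spec$mito_base * mito$potential[i]
    }
  }
  if (nrow(puncta)) {
    for (i in seq_len(nrow(puncta))) {
      p <- puncta[i, ]
      for (ch in if (p$channel == "dual") c("gfp", "rfp") else p$channel) {
        channels[[ch]] <- render_punctum(channels[[ch]], p$row, p$col,
                                         p$sigma, p$amplitude)
      }
    }
  }
  if (spec$noise_gain > 0 || spec$read_noise_sd > 0) {
    channels <- lapply(channels, apply_camera_noise,
                       gain = spec$noise_gain, read_sd = spec$read_noise_sd)
  }
  dual <- puncta[puncta$channel == "dual", , drop = FALSE]
  truth <- structure(list(
    puncta = puncta, mito = mito, cell = cell, cell_mask = cell_mask,
    expected = list(n_dual = nrow(dual),
                    n_dual_near_mito = sum(dual$near_mito, na.rm = TRUE))
  ), class = "scene_truth")
  scene <- structure(list(channels = channels,
                          pixel_size_nm = spec$pixel_size_nm,
                          image_size = dim, seed = spec$seed),
                     class = "scene")
  list(scene = scene, truth = truth)
}

#' Ground-truth pixel footprint of a punctum
#'
#' The disc of pixels within two spot standard deviations of a punctum
#' center, used when ground-truth association labels are recomputed with
#' the measurement-side edge-distance metric.
#'
#' @param punctum One row of a truth `puncta` tibble.
#' @param dim Image dimensions.
#' @return Integer pixel-set matrix.
#' @export
punctum_truth_pixels <- function(punctum, dim) {
  truth_pixels(punctum, dim)
}

#' Simulate a ground-truthed time-lapse movie
#'
#' Renders `n_timepoints` frames of `n_zslices` scenes each. The whole
#' cell (mask, mitochondria, puncta) is rigidly translated by
#' `drift_px_per_frame` per timepoint, with optional per-timepoint puncta
#' jitter; Z-slices share a timepoint's geometry but receive independent
#' noise. A frame is marked invalid in the ground truth when the cell,
#' widened by the mask-refinement margin (8 px), touches the image border.
#'
#' @param tspec A [timelapse_spec()].
#' @return List with `frames` (list over timepoints; each a list over
#'   Z-slices of `scene` objects), `truth` (list of per-timepoint
#'   `scene_truth`), and `validity` (tibble: `t`, `valid`, `reason`).
#' @export
simulate_timelapse <- function(tspec = timelapse_spec()) {
  stopifnot(inherits(tspec, "timelapse_spec"))
  withr::with_seed(tspec$scene$seed, {
    spec <- tspec$scene
    base <- list(center = spec$cell_center, axes = spec$cell_axes,
                 theta = spec$cell_theta)
    mito0 <- place_mito(spec, base)
    puncta0 <- place_puncta(spec, base, mito0)
    frames <- vector("list", tspec$n_timepoints)
    truths <- vector("list", tspec$n_timepoints)
    val <- tibble(t = seq_len(tspec$n_timepoints), valid = TRUE,
                  reason = "none")
    for (t in seq_len(tspec$n_timepoints)) {
      off <- (t - 1) * tspec$drift_px_per_frame
      center_t <- spec$cell_center + off
      mito_t <- mito0
      if (nrow(mito_t)) {
        mito_t$pixels <- lapply(mito0$pixels, function(px) {
          px2 <- cbind(row = px[, 1] + round(off[1]),
                       col = px[, 2] + round(off[2]))
          px2[px2[, 1] >= 1 & px2[, 1] <= spec$image_size[1] &
              px2[, 2] >= 1 & px2[, 2] <= spec$image_size[2], , drop = FALSE]
        })
      }
      puncta_t <- puncta0
      if (nrow(puncta_t)) {
        puncta_t$row <- puncta_t$row + off[1]
        puncta_t$col <- puncta_t$col + off[2]
        if (tspec$puncta_motion_px > 0) {
          puncta_t$row <- puncta_t$row +
            stats::rnorm(nrow(puncta_t), 0, tspec$puncta_motion_px)
          puncta_t$col <- puncta_t$col +
            stats::rnorm(nrow(puncta_t), 0, tspec$puncta_motion_px)
        }
      }
      border <- cell_touches_border(center_t, spec$cell_axes, spec$cell_theta,
                                    spec$image_size, widen_px = 8)
      if (border) { val$valid[t] <- FALSE; val$reason[t] <- "touches_border" }
      zs <- vector("list", tspec$n_zslices)
      for (z in seq_len(tspec$n_zslices)) {
        out <- simulate_scene_impl(spec, cell_center = center_t,
                                   puncta = puncta_t, mito = mito_t)
        zs[[z]] <- out$scene
        if (z == 1) truths[[t]] <- out$truth
      }
      frames[[t]] <- zs
    }
    list(frames = frames, truth = truths, validity = val,
         z_spacing_nm = tspec$z_spacing_nm)
  })
}

# Geometric ground truth for border rejection: does the cell ellipse,
# widened by `widen_px` (the mask dilation margin), reach the border rows
# or columns of the image?
cell_touches_border <- function(center, axes, theta, dim, widen_px = 8) {
  b <- ellipse_boundary(center, axes, theta)
  reach_r <- range(b[, 1]); reach_c <- range(b[, 2])
  (reach_r[1] - widen_px) <= 1 || (reach_r[2] + widen_px) >= dim[1] ||
    (reach_c[1] - widen_px) <= 1 || (reach_c[2] + widen_px) >= dim[2]
}
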