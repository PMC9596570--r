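# Internal helpers shared across modules. Images are plain numeric matrices
# indexed [row, col], 1-based. Pixel sets are integer matrices with columns
# row, col.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

assert_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    abort(paste0("`", arg, "` must be a numeric matrix"))
  }
  if (!all(is.finite(frame))) {
    abort(paste0("`", arg, "` contains non-finite pixels"))
  }
  invisible(frame)
}

# Reflect-pad a matrix by `pad` pixels on every side.
pad_reflect <- function(x, pad) {
  n <- nrow(x); m <- ncol(x)
  if (pad >= n || pad >= m) abort("padding exceeds image size")
  x <- rbind(x[pad:1, , drop = FALSE], x, x[n:(n - pad + 1), , drop = FALSE])
  cbind(x[, pad:1, drop = FALSE], x, x[, m:(m - pad + 1), drop = FALSE])
}

# 2-D correlation with a centered odd-sized kernel, reflective boundary.
# EBImage::filter2 is FFT-based with circular boundary; padding by the kernel
# radius makes the result equal to direct correlation with reflection.
convolve_reflect <- function(x, kernel) {
  pad <- (nrow(kernel) - 1L) / 2L
  xp <- pad_reflect(x, pad)
  out <- EBImage::imageData(EBImage::filter2(xp, kernel, boundary = "circular"))
  out[(pad + 1L):(pad + nrow(x)), (pad + 1L):(pad + ncol(x)), drop = FALSE]
}

gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  ax <- (-radius):radius
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

gaussian_blur <- function(x, sigma) {
  convolve_reflect(x, gaussian_kernel(sigma))
}

# Logical mask -> pixel-set matrix (cols row, col).
mask_to_pixels <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

pixels_to_mask <- function(pixels, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  if (nrow(pixels)) m[cbind(pixels[, 1], pixels[, 2])] <- TRUE
  m
}

# Linear indices of a pixel set within an image of given dim.
pixels_linear <- function(pixels, dim) {
  (as.integer(pixels[, 2]) - 1L) * dim[1] + as.integer(pixels[, 1])
}

# Rotated-ellipse membership for pixel grid; returns logical matrix.
ellipse_mask <- function(dim, center, semi_axes, theta = 0) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dr <- r - center[1]; dc <- c - center[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

# Dense boundary sample of a rotated ellipse (row, col coordinates).
ellipse_boundary <- function(center, semi_axes, theta = 0, n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- semi_axes[1] * cos(t); v <- semi_axes[2] * sin(t)
  cbind(row = center[1] + u * cos(theta) - v * sin(theta),
        col = center[2] + u * sin(theta) + v * cos(theta))
}

# Disc of pixel centers within `radius` of a (possibly fractional) center.
disc_pixels <- function(center, radius, dim = NULL) {
  r0 <- floor(center[1] - radius):ceiling(center[1] + radius)
  c0 <- floor(center[2] - radius):ceiling(center[2] + radius)
  g <- expand.grid(row = r0, col = c0)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  if (!is.null(dim)) {
    g <- g[g$row >= 1 & g$row <= dim[1] & g$col >= 1 & g$col <= dim[2], ,
           drop = FALSE]
  }
  as.matrix(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
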