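#' Cohen's d between an object's and the cell's intensity distribution
#'
#' Pooled-SD standardized mean difference,
#' \eqn{d = (\bar x_{obj} - \bar x_{cell}) / s_{pooled}} with
#' \eqn{s_{pooled}^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}.
#' With zero pooled SD, `d` is 0 for equal means and signed infinity
#' otherwise. Fewer than 3 pixels overall leave `d` undefined (`NA`); the
#' calling filter then discards the object conservatively.
#'
#' @param object_pixels Intensities of the object's pixels.
#' @param cell_pixels Intensities of all pixels in the valid cell mask.
#' @return A single numeric effect size.
#' @export
cohens_d <- function(object_pixels, cell_pixels) {
  stopifnot(length(object_pixels) >= 1, length(cell_pixels) >= 1)
  n1 <- length(object_pixels); n2 <- length(cell_pixels)
  if (n1 + n2 < 3) return(NA_real_)
  m1 <- mean(object_pixels); m2 <- mean(cell_pixels)
  v1 <- if (n1 > 1) stats::var(object_pixels) else 0
  v2 <- if (n2 > 1) stats::var(cell_pixels) else 0
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / sp
}

#' Live-cell false-positive filters
#'
#' Prunes a high-recall (autotuned) detection with the three object-level
#' filters: (1) discard objects whose intensity distribution has negative
#' Cohen's d against the cell's; (2) require each object's peak intensity
#' to be an upper outlier of the cell intensity distribution
#' (above `Q3 + 1.5 * IQR`, quartiles by linear interpolation); (3)
#' discard objects of 4 pixels or less, unobservable at the 2-px system
#' precision. The cell distribution is all pixels inside the valid cell
#' mask (object pixels included).
#'
#' @param objects Object tibble from [detect_puncta()] /
#'   [autotune_detect()].
#' @param cell_mask A valid `cell_mask` (or logical matrix).
#' @param frame The intensity frame the objects were detected in.
#' @return A list: `kept` (objects passing all three filters) and
#'   `records` — one row per input object with `id`, `cohens_d`,
#'   `peak_intensity`, `cell_q3`, `cell_iqr`, `passed_effect_size`,
#'   `passed_peak_outlier`, `passed_area`.
#' @export
apply_qc <- function(objects, cell_mask, frame) {
  m <- if (inherits(cell_mask, "cell_mask")) cell_mask$mask else cell_mask
  if (!any(m)) abort("empty cell mask")
  cell_int <- frame[m]
  q <- stats::quantile(cell_int, c(0.25, 0.75), names = FALSE, type = 7)
  fence_q3 <- q[2]
  fence_iqr <- q[2] - q[1]
  d <- vapply(objects$intensities, function(x) cohens_d(x, cell_int), 0)
  records <- tibble(
    id = objects$id,
    cohens_d = d,
    peak_intensity = objects$max_intensity,
    cell_q3 = fence_q3,
    cell_iqr = fence_iqr,
    passed_effect_size = !is.na(d) & d >= 0,
    passed_peak_outlier = objects$max_intensity > fence_q3 + 1.5 * fence_iqr,
    passed_area = objects$area_px > 4
  )
  keep <- records$passed_effect_size & records$passed_peak_outlier &
    records$passed_area
  list(kept = objects[keep, , drop = FALSE], records = records)
}
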