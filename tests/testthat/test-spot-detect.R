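test_that("LoG response is zero on constant frames and matches dense convolution", {
  const <- matrix(5, 32, 32)
  expect_lt(max(abs(log_filter(const, 3))), 1e-9)

  # single Gaussian blob of matching sigma: argmax at the blob center
  blob <- function(dim, r0, c0, sigma, A = 10) {
    r <- matrix(seq_len(dim[1]), dim[1], dim[2])
    c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    A * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2))
  }
  x <- blob(c(64, 64), 25, 40, 3)
  resp <- log_filter(x, 3)
  expect_equal(as.vector(which(resp == max(resp), arr.ind = TRUE)), c(25, 40))
  # matches a dense direct-convolution oracle on the full 64x64 frame
  k <- punctaflux:::log_kernel(3)
  expect_equal(resp, oracle_convolve(x, k), tolerance = 1e-8)

  # linearity: two well-separated blobs sum their responses
  x1 <- blob(c(64, 64), 16, 16, 3); x2 <- blob(c(64, 64), 48, 48, 3)
  expect_equal(log_filter(x1 + x2, 3), log_filter(x1, 3) + log_filter(x2, 3),
               tolerance = 1e-6)
  expect_error(log_filter(matrix(c(1, NA, 1, 1), 2, 2), 3), "non-finite")
})

test_that("adaptive threshold is mu + z*sd and monotone in z", {
  # hand-built 5x5 grid: 24 zeros and one spike
  resp <- matrix(0, 5, 5)
  resp[3, 3] <- 10
  mu <- mean(resp); s <- sd(resp)
  # the spike sits at (10 - mu)/s = 4.9 sd; in mask at z = 1.75, out at z = 6
  expect_true(threshold_response(resp, 1.75)[3, 3])
  expect_equal(sum(threshold_response(resp, 1.75)), 1)
  expect_false(threshold_response(resp, (10 - mu) / s + 0.01)[3, 3])
  # z -> infinity empties the mask
  expect_equal(sum(threshold_response(resp, 1e6)), 0)
  # zero variance: empty mask with a warning, not an error
  expect_warning(m0 <- threshold_response(matrix(1, 4, 4), 1.75),
                 "zero response variance")
  expect_equal(sum(m0), 0)
  # support restricts the statistics: excluding the spike lowers the bar
  resp[1, 1] <- 2
  supp <- matrix(TRUE, 5, 5); supp[3, 3] <- FALSE
  m <- threshold_response(resp, 1, supp)
  expect_true(m[3, 3])
  expect_true(m[1, 1])
  expect_equal(sum(m), 2)
})

test_that("masks are pixelwise nested and counts non-increasing across z", {
  sim <- simulate_scene(test_scene_spec(seed = 21))
  resp <- log_filter(sim$scene$channels$gfp, 3)
  zs <- c(0.5, 1, 1.75, 2.5, 6, 12)
  masks <- lapply(zs, threshold_response, response = resp,
                  support = sim$truth$cell_mask)
  for (i in seq_len(length(zs) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]])) # mask(z) contains mask(z')
  }
  counts <- vapply(masks, function(m)
    nrow(filter_min_area(label_objects(m, sim$scene$channels$gfp), 25)), 0L)
  expect_false(is.unsorted(rev(counts)))
  expect_equal(counts[length(counts)], 0L)
})

test_that("detection is invariant to affine intensity rescaling", {
  sim <- simulate_scene(test_scene_spec(seed = 22))
  x <- sim$scene$channels$gfp
  m1 <- threshold_response(log_filter(x, 3), 1.75, sim$truth$cell_mask)
  m2 <- threshold_response(log_filter(2.7 * x + 31, 3), 1.75,
                           sim$truth$cell_mask)
  expect_identical(m1, m2)
})

test_that("labeling follows the declared connectivity and a flood-fill oracle", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  f <- matrix(1, 4, 4)
  expect_equal(nrow(label_objects(m, f, connectivity = 8)), 1)
  expect_equal(nrow(label_objects(m, f, connectivity = 4)), 2)
  expect_equal(nrow(label_objects(matrix(FALSE, 3, 3), matrix(0, 3, 3))), 0)

  set.seed(99)
  for (i in 1:50) {
    mask <- matrix(runif(24 * 24) < 0.3, 24, 24)
    frame <- matrix(rnorm(24 * 24), 24, 24)
    for (conn in c(4, 8)) {
      expect_equal(nrow(label_objects(mask, frame, connectivity = conn)),
                   oracle_count_components(mask, conn))
    }
  }
})

test_that("objects carry intensities from the frame, not the response", {
  frame <- matrix(0, 6, 6)
  frame[2:3, 2:3] <- c(5, 7, 6, 9)
  mask <- frame > 0
  obj <- label_objects(mask, frame)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area_px, 4L)
  expect_equal(obj$max_intensity, 9)
  expect_equal(obj$mean_intensity, mean(c(5, 7, 6, 9)))
  expect_equal(sort(obj$intensities[[1]]), c(5, 6, 7, 9))
  expect_equal(obj$centroid_row, 2.5)
})

test_that("area filter removes objects at or below the threshold", {
  mk <- function(areas) tibble::tibble(id = seq_along(areas), area_px = areas)
  expect_equal(nrow(filter_min_area(mk(25), 25)), 0)  # 25 px or less: removed
  expect_equal(nrow(filter_min_area(mk(26), 25)), 1)
  expect_equal(nrow(filter_min_area(mk(4), 4)), 0)    # live mode boundary
  expect_equal(nrow(filter_min_area(mk(c(24, 25, 26)), 25,
                                    inclusive = FALSE)), 2)
})

test_that("detection recovers simulated puncta and autotune lowers the bar", {
  sim <- simulate_scene(test_scene_spec(seed = 23))
  tr <- sim$truth
  p <- detection_params(support = tr$cell_mask)
  det <- clip_to_cell(detect_puncta(sim$scene$channels$gfp, p, "gfp"),
                      tr$cell_mask)
  truth_g <- tr$puncta[tr$puncta$channel %in% c("gfp", "dual"), ]
  m <- match_to_truth(det, truth_g)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["precision"]], 1)

  # ratio = 1 reproduces the default-z detection up to the live area filter
  d1 <- autotune_detect(sim$scene$channels$gfp, ratio = 1, p)
  d2 <- detect_puncta(sim$scene$channels$gfp,
                      detection_params(min_area_px = 4, support = tr$cell_mask))
  expect_equal(d1$centroid_row, d2$centroid_row)
  # high-recall mode never finds fewer objects
  d3 <- autotune_detect(sim$scene$channels$gfp, ratio = 3.75, p)
  expect_gte(nrow(d3), nrow(d1))
})
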