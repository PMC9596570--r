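test_that("ratios are exact on constructed segments", {
  # punctum covering the entire single-segment network: both ratios 1
  seg <- as.matrix(expand.grid(row = 3:5, col = 3:8))
  frame <- matrix(0, 10, 10); frame[seg] <- 120
  mito <- tibble::tibble(id = 1L, pixels = list(seg))
  dual_all <- tibble::tibble(id = 1L, pixels = list(seg),
                             centroid_row = 4, centroid_col = 5)
  rr <- compute_ratios(dual_all, mito, frame)
  expect_equal(rr$ratio_segment, 1)
  expect_equal(rr$ratio_cell, 1)

  # 10 px at 100 and 10 px at 50; punctum on the 50-valued half
  seg2 <- cbind(row = rep(1:4, 5), col = rep(1:5, each = 4))[1:20, ]
  f2 <- matrix(0, 10, 10)
  f2[seg2] <- rep(c(100, 50), each = 10)
  mito2 <- tibble::tibble(id = 1L, pixels = list(seg2))
  dual2 <- tibble::tibble(id = 1L, pixels = list(seg2[11:20, ]),
                          centroid_row = 2, centroid_col = 4)
  rr2 <- compute_ratios(dual2, mito2, f2)
  expect_equal(rr2$overlap_mean, 50)
  expect_equal(rr2$segment_mean, 75)
  expect_identical(rr2$ratio_segment, 50 / 75)

  # punctum with no mito overlap yields no record
  dual_off <- tibble::tibble(id = 2L, pixels = list(cbind(row = 9, col = 9)),
                             centroid_row = 9, centroid_col = 9)
  expect_equal(nrow(compute_ratios(dual_off, mito2, f2)), 0)

  # tie in overlap size resolved by nearest segment centroid
  segA <- cbind(row = 1:4, col = 1)   # centroid (2.5, 1)
  segB <- cbind(row = 1:4, col = 9)   # centroid (2.5, 9)
  f3 <- matrix(0, 10, 10); f3[segA] <- 10; f3[segB] <- 40
  mito3 <- tibble::tibble(id = c(1L, 2L), pixels = list(segA, segB))
  dual3 <- tibble::tibble(id = 1L,
                          pixels = list(rbind(cbind(row = 1, col = 1),
                                              cbind(row = 1, col = 9))),
                          centroid_row = 1, centroid_col = 8) # nearer segB
  rr3 <- compute_ratios(dual3, mito3, f3)
  expect_equal(rr3$mito_id, 2L)
  expect_equal(rr3$segment_mean, 40)
})

test_that("ratios are invariant to positive rescaling of the mito frame", {
  sim <- simulate_scene(test_scene_spec(seed = 51, frac_near_mito = 1))
  duals <- truth_dual_objects(sim$truth, sim$scene$image_size)
  r1 <- compute_ratios(duals, sim$truth$mito, sim$scene$channels$mito)
  r2 <- compute_ratios(duals, sim$truth$mito, 7.3 * sim$scene$channels$mito)
  expect_equal(r1$ratio_cell, r2$ratio_cell, tolerance = 1e-12)
  expect_equal(r1$ratio_segment, r2$ratio_segment, tolerance = 1e-12)
})

test_that("boxplot summaries match a sort-based quantile oracle", {
  one <- tibble::tibble(dual_id = 1L, ratio_segment = 0.8, ratio_cell = 0.8)
  s1 <- summarize_ratios(one)
  expect_equal(s1$median, c(0.8, 0.8))
  expect_equal(s1$q1, c(0.8, 0.8))

  three <- tibble::tibble(dual_id = 1:3, ratio_segment = c(0.5, 1, 1.5),
                          ratio_cell = c(0.5, 1, 1.5))
  expect_equal(summarize_ratios(three)$median, c(1, 1))

  set.seed(60)
  vals <- rlnorm(1000, 0, 0.4)
  big <- tibble::tibble(dual_id = seq_along(vals), ratio_segment = vals,
                        ratio_cell = vals)
  sb <- summarize_ratios(big)
  expect_equal(sb$median[1], oracle_quantile7(vals, 0.5), tolerance = 1e-12)
  expect_equal(sb$q1[1], oracle_quantile7(vals, 0.25), tolerance = 1e-12)
  expect_equal(sb$q3[1], oracle_quantile7(vals, 0.75), tolerance = 1e-12)
  expect_equal(sb$n[1], 1000L)
  expect_true(all(sb$q1 <= sb$median & sb$median <= sb$q3))
})

test_that("uniformly placed puncta give median cell ratio near 1", {
  # 50 constructed segments with uniform potentials; 500 puncta dropped on
  # random segments independently of potential
  set.seed(61)
  n_seg <- 50
  frame <- matrix(0, 220, 60)
  segs <- list(); pots <- runif(n_seg, 0.5, 1)
  for (i in seq_len(n_seg)) {
    rows <- (4 * i - 3):(4 * i - 1)
    px <- as.matrix(expand.grid(row = rows, col = 10:39))
    frame[px] <- 150 * pots[i]
    segs[[i]] <- px
  }
  mito <- tibble::tibble(id = seq_len(n_seg), pixels = segs)
  duals <- dplyr::bind_rows(lapply(1:500, function(k) {
    i <- sample.int(n_seg, 1)
    cols <- sample(10:32, 1)
    tibble::tibble(id = k,
                   pixels = list(as.matrix(expand.grid(
                     row = (4 * i - 3):(4 * i - 1), col = cols:(cols + 7)))),
                   centroid_row = 4 * i - 2, centroid_col = cols + 3.5)
  }))
  rr <- compute_ratios(duals, mito, frame)
  expect_equal(nrow(rr), 500)
  expect_lt(abs(median(rr$ratio_cell) - 1), 0.1)
})

test_that("puncta stratified onto dim segments push the median below 1", {
  meds <- vapply(1:5, function(s) {
    sim <- simulate_scene(scene_spec(
      image_size = c(240, 240), n_gfp_only = 0, n_rfp_only = 0, n_dual = 4,
      frac_near_mito = 1, mito_n_segments = 6,
      mito_potentials = rep(c(0.5, 1), 3), near_mito_segments = c(1, 3, 5),
      min_separation_px = 9, seed = s))
    duals <- truth_dual_objects(sim$truth, sim$scene$image_size)
    rr <- compute_ratios(duals, sim$truth$mito, sim$scene$channels$mito)
    median(rr$ratio_cell)
  }, 0)
  expect_true(all(meds < 1))
})

test_that("zero-mean segments drop the record with a warning", {
  seg <- cbind(row = 1:4, col = 1)
  frame <- matrix(0, 6, 6) # mito-positive pixels with zero intensity
  mito <- tibble::tibble(id = 1L, pixels = list(seg))
  dual <- tibble::tibble(id = 1L, pixels = list(seg),
                         centroid_row = 2, centroid_col = 1)
  expect_warning(rr <- compute_ratios(dual, mito, frame), "zero segment")
  expect_equal(nrow(rr), 0)
})
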