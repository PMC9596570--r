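mk_obj <- function(id, pixels, channel = "x") {
  n <- nrow(pixels)
  tibble::tibble(id = id, channel = channel, area_px = n,
                 centroid_row = mean(pixels[, 1]),
                 centroid_col = mean(pixels[, 2]),
                 mean_intensity = 1, max_intensity = 1,
                 pixels = if (n) list(pixels) else list(),
                 intensities = if (n) list(rep(1, n)) else list())
}
px_rect <- function(r, c) as.matrix(expand.grid(row = r, col = c))

test_that("dual puncta are unions of cross-channel overlapping objects", {
  g1 <- mk_obj(1L, px_rect(1:3, 1:3), "gfp")
  r_far <- mk_obj(1L, px_rect(8:9, 8:9), "rfp")
  expect_equal(nrow(build_dual_puncta(g1, r_far, dim = c(10, 10))), 0)

  # exactly one shared pixel: union area |G| + |R| - 1
  r1 <- mk_obj(1L, px_rect(3:5, 3:5), "rfp")
  d <- build_dual_puncta(g1, r1, dim = c(10, 10))
  expect_equal(nrow(d), 1)
  expect_equal(d$area_px, 9 + 9 - 1)

  # one mRFP object bridging two GFP objects: a single dual punctum of 3
  ga <- mk_obj(1L, px_rect(1:2, 1:2), "gfp")
  gb <- mk_obj(2L, px_rect(1:2, 6:7), "gfp")
  rb <- mk_obj(1L, px_rect(2, 2:6), "rfp")
  gfp <- dplyr::bind_rows(ga, gb)
  d2 <- build_dual_puncta(gfp, rb, dim = c(10, 10))
  expect_equal(nrow(d2), 1)
  expect_setequal(d2$gfp_ids[[1]], c(1L, 2L))
  expect_equal(d2$area_px, nrow(unique(rbind(ga$pixels[[1]], gb$pixels[[1]],
                                             rb$pixels[[1]]))))
})

test_that("minimum edge distance equals the exhaustive all-pairs oracle", {
  a <- px_rect(1:2, 1:2)
  expect_equal(min_edge_distance(a, a), 0)
  expect_equal(min_edge_distance(cbind(0, 0), cbind(3, 4)), 5)
  expect_error(min_edge_distance(a, a[0, , drop = FALSE]), "empty")

  set.seed(17)
  for (i in 1:200) {
    a <- random_pixels(sample(1:12, 1))
    b <- random_pixels(sample(1:12, 1))
    expect_identical(min_edge_distance(a, b), oracle_min_distance(a, b))
    expect_identical(min_edge_distance(a, b), min_edge_distance(b, a))
  }
  # triangle inequality on singleton sets
  set.seed(18)
  for (i in 1:50) {
    p <- matrix(sample(1:50, 6, TRUE), 3, 2)
    d_ab <- min_edge_distance(p[1, , drop = FALSE], p[2, , drop = FALSE])
    d_bc <- min_edge_distance(p[2, , drop = FALSE], p[3, , drop = FALSE])
    d_ac <- min_edge_distance(p[1, , drop = FALSE], p[3, , drop = FALSE])
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("association uses the inclusive 5-pixel resolution cutoff", {
  dual <- tibble::tibble(id = 1L, pixels = list(cbind(row = 5, col = 5)),
                         centroid_row = 5, centroid_col = 5)
  mito_at <- function(row, col) mk_obj(1L, cbind(row = row, col = col), "mito")

  overlap <- associate_with_mito(dual, mito_at(5, 5))
  expect_equal(overlap$edge_distance_px, 0)
  expect_true(overlap$associated)

  at5 <- associate_with_mito(dual, mito_at(8, 9)) # 3-4-5: exactly 5
  expect_equal(at5$edge_distance_px, 5)
  expect_true(at5$associated)                      # within or equal

  past5 <- associate_with_mito(dual, mito_at(5, 11)) # distance 6
  expect_false(past5$associated)

  none <- associate_with_mito(dual, mk_obj(integer(0),
                                           px_rect(1, 1)[0, , drop = FALSE]))
  expect_true(is.na(none$nearest_mito_id))
  expect_false(none$associated)
})

test_that("end-to-end association recovers the ground-truth labels", {
  for (s in c(41, 42)) {
    sim <- simulate_scene(test_scene_spec(seed = s, frac_near_mito = 1))
    tr <- sim$truth
    p <- detection_params(support = tr$cell_mask)
    gfp <- clip_to_cell(detect_puncta(sim$scene$channels$gfp, p, "gfp"),
                        tr$cell_mask)
    rfp <- clip_to_cell(detect_puncta(sim$scene$channels$rfp, p, "rfp"),
                        tr$cell_mask)
    mito <- detect_puncta(sim$scene$channels$mito,
                          detection_params(min_area_px = 0,
                                           support = tr$cell_mask), "mito")
    duals <- build_dual_puncta(gfp, rfp, dim = sim$scene$image_size)
    recs <- associate_with_mito(duals, mito)
    truth_d <- tr$puncta[tr$puncta$channel == "dual", ]
    m <- match_to_truth(duals, truth_d)
    expect_equal(m[["recall"]], 1)
    expect_true(all(recs$associated))
  }
})

test_that("per-cell summaries recount the record lists exactly", {
  empty <- summarize_cell(punctaflux:::empty_objects(),
                          punctaflux:::empty_objects(),
                          tibble::tibble(id = integer(0)),
                          associate_with_mito(
                            tibble::tibble(id = integer(0), pixels = list(),
                                           centroid_row = numeric(0),
                                           centroid_col = numeric(0)),
                            punctaflux:::empty_objects()))
  expect_equal(empty$n_dual, 0)
  expect_true(is.na(empty$fraction_near_mito))

  duals <- tibble::tibble(id = 1:10)
  recs <- tibble::tibble(dual_id = 1:10, nearest_mito_id = 1L,
                         edge_distance_px = c(rep(1, 5), rep(9, 5)),
                         associated = c(rep(TRUE, 5), rep(FALSE, 5)))
  s <- summarize_cell(punctaflux:::empty_objects(),
                      punctaflux:::empty_objects(), duals, recs)
  expect_equal(s$n_dual, 10)
  expect_equal(s$n_dual_near_mito, 5L)
  expect_equal(s$fraction_near_mito, 0.5)
  expect_equal(s$n_dual_near_mito, sum(recs$edge_distance_px <= 5))

  # association counts are invariant to object id relabeling
  perm <- sample(10)
  recs2 <- recs; recs2$dual_id <- perm
  s2 <- summarize_cell(punctaflux:::empty_objects(),
                       punctaflux:::empty_objects(),
                       duals[order(perm), ], recs2)
  expect_equal(s2$n_dual_near_mito, s$n_dual_near_mito)
})

test_that("objects straddling the cell edge are kept at >= 50% inside", {
  mask <- matrix(FALSE, 10, 10); mask[, 1:5] <- TRUE
  inside <- mk_obj(1L, px_rect(1:2, 1:2))
  half <- mk_obj(2L, px_rect(1:2, 5:6))     # 2 of 4 pixels inside
  mostly_out <- mk_obj(3L, px_rect(1:2, 5:7)) # 2 of 6 inside
  objs <- dplyr::bind_rows(inside, half, mostly_out)
  kept <- clip_to_cell(objs, mask)
  expect_equal(kept$id, c(1L, 2L))
})
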