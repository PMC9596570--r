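# Shared fixtures and independent oracles. Oracles are deliberately naive
# (dense loops, recursion) and never call the code paths they check.

# small, fast default scene used across tests
test_scene_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(image_size = c(256, 256), n_gfp_only = 2, n_rfp_only = 2,
         n_dual = 4, mito_n_segments = 3, seed = seed),
    list(...))
  do.call(scene_spec, args)
}

# random pixel set of n pixels on a grid
random_pixels <- function(n, lim = 30) {
  cbind(row = sample.int(lim, n, replace = TRUE),
        col = sample.int(lim, n, replace = TRUE))
}

# the recovery-study fixture: 30 dual puncta at peak SNR 5 in a large cell
recovery_spec <- function(seed) {
  scene_spec(image_size = c(480, 480), n_gfp_only = 0, n_rfp_only = 0,
             n_dual = 30, puncta_peak_snr = 5, frac_near_mito = 0.5,
             mito_n_segments = 8, seed = seed)
}

# dense direct correlation (reflect boundary), O(n^2 k^2)
oracle_convolve <- function(x, k) {
  r <- (nrow(k) - 1) / 2
  n <- nrow(x); m <- ncol(x)
  reflect <- function(i, n) { i <- ifelse(i < 1, 1 - i, i)
                              ifelse(i > n, 2 * n + 1 - i, i) }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + x[reflect(i + a, n), reflect(j + b, m)] * k[a + r + 1, b + r + 1]
    }
    out[i, j] <- acc
  }
  out
}

# recursive flood fill, independent of the igraph labeling
oracle_count_components <- function(mask, connectivity = 8) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  n
}

# exhaustive all-pairs pixel distance
oracle_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  }
  best
}

# match detected centroids to ground-truth centers within a radius;
# returns recall, precision and the worst matched centroid error
match_to_truth <- function(objects, truth, radius = 3) {
  if (!nrow(objects) || !nrow(truth)) {
    return(c(recall = 0, precision = 0, max_err = NA))
  }
  d2 <- outer(objects$centroid_row, truth$row, "-")^2 +
    outer(objects$centroid_col, truth$col, "-")^2
  truth_best <- apply(d2, 2, min)
  det_best <- apply(d2, 1, min)
  c(recall = mean(truth_best <= radius^2),
    precision = mean(det_best <= radius^2),
    max_err = sqrt(max(truth_best[truth_best <= radius^2])))
}

# ground-truth dual puncta as measurement-ready pixel-set objects
truth_dual_objects <- function(truth, dim) {
  d <- truth$puncta[truth$puncta$channel == "dual", , drop = FALSE]
  tibble::tibble(
    id = seq_len(nrow(d)),
    pixels = lapply(seq_len(nrow(d)), function(i)
      punctum_truth_pixels(d[i, ], dim)),
    centroid_row = d$row, centroid_col = d$col)
}

# type-7 (linear interpolation) quantile by direct sort-and-index
oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# tie-corrected Kruskal-Wallis H by direct rank arithmetic
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups); N <- length(x)
  r <- rank(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), 0)) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# two-group permutation p-value for H (B label shuffles)
oracle_perm_p <- function(a, b, B = 20000) {
  x <- c(a, b); N <- length(x); n1 <- length(a)
  r <- rank(x)
  ties <- table(x); C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  hfun <- function(w1) {
    (12 / (N * (N + 1)) * (w1^2 / n1 + (sum(r) - w1)^2 / (N - n1)) -
       3 * (N + 1)) / C
  }
  hobs <- hfun(sum(r[seq_len(n1)]))
  hp <- vapply(seq_len(B), function(i) hfun(sum(r[sample.int(N, n1)])), 0)
  mean(hp >= hobs - 1e-12)
}
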