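test_that("polygon_from_rays places vertices on the ray directions", {
  p <- polygon_from_rays(c(0, 0), rep(1, 4), 4)
  expect_equal(unname(p),
               cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)), tolerance = 1e-12)
  expect_equal(nucleograde:::cpp_polygon_area(p), 2)
  # circle limit: area -> pi r^2
  p360 <- polygon_from_rays(c(5, 5), rep(10, 360), 360)
  expect_lt(abs(nucleograde:::cpp_polygon_area(p360) - 100 * pi) /
              (100 * pi), 1e-3)
  expect_error(polygon_from_rays(c(0, 0), c(1, 0, 1, 1)), "positive")
})

test_that("polygon_iou is exact on known configurations", {
  sq <- function(x0, y0, s = 1)
    cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
  expect_equal(polygon_iou(sq(0, 0), sq(0, 0)), 1)
  expect_equal(polygon_iou(sq(0, 0), sq(3, 3)), 0)
  # unit squares overlapping by half: 0.5 / (2 - 0.5) = 1/3
  expect_equal(polygon_iou(sq(0, 0), sq(0.5, 0)), 1 / 3)
  # symmetry and non-convex star shapes
  set.seed(4)
  for (k in 1:20) {
    r1 <- runif(16, 3, 10); r2 <- runif(16, 3, 10)
    a <- polygon_from_rays(c(0, 0), r1)
    b <- polygon_from_rays(runif(2, -4, 4), r2)
    expect_equal(polygon_iou(a, b), polygon_iou(b, a), tolerance = 1e-10)
    expect_gte(polygon_iou(a, b), 0)
    expect_lte(polygon_iou(a, b), 1)
  }
  # degenerate zero-area polygon
  degen <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_equal(polygon_iou(degen, sq(0, 0)), 0)
})

test_that("non-convex IoU agrees with a Monte-Carlo area oracle", {
  set.seed(9)
  r1 <- 8 * (1 + 0.4 * cos(3 * 2 * pi * (0:31) / 32))
  r2 <- 7 * (1 + 0.3 * sin(2 * 2 * pi * (0:31) / 32))
  a <- polygon_from_rays(c(0, 0), r1)
  b <- polygon_from_rays(c(4, 2), r2)
  xs <- runif(2e5, -15, 15); ys <- runif(2e5, -15, 15)
  ina <- nucleograde:::cpp_points_in_poly(xs, ys, a)
  inb <- nucleograde:::cpp_points_in_poly(xs, ys, b)
  mc <- sum(ina & inb) / sum(ina | inb)
  expect_lt(abs(polygon_iou(a, b) - mc), 0.01)
})

test_that("compute_maps: blank tile has no objects, disc has radius ~10", {
  maps <- compute_maps(blank_white_tile())
  expect_lt(max(maps$prob), 0.1)
  expect_length(maps$fg_idx, 0)

  maps <- compute_maps(disc_tile(r = 10), n_rays = 8, smooth_sigma = 0)
  # distances at the disc centre: ~10 along all 8 rays
  centre_idx <- which(maps$fg_idx == (32 * 64 + 32 + 1))
  expect_length(centre_idx, 1)
  expect_true(all(abs(maps$dist[centre_idx, ] - 10) < 1.2))
  expect_true(all(maps$dist >= 0))
  expect_true(all(maps$prob >= 0 & maps$prob <= 1))
  expect_error(compute_maps(matrix(1, 5, 5)), "RGB")
})

test_that("probability is higher at planted centers than background", {
  tile <- small_tile(n_cells = 100, seed = 2)
  maps <- compute_maps(tile$image)
  ctr <- round(tile$truth$centers_um / 0.5)  # back to px
  p_ctr <- maps$prob[cbind(ctr[, 2] + 1, ctr[, 1] + 1)]
  bg <- maps$prob[tile$truth$instance_mask == 0]
  expect_gte(mean(p_ctr > quantile(bg, 0.99)), 0.95)
})

test_that("candidates honour threshold, stride and sort contract", {
  tile <- disc_tile(r = 8)
  maps <- compute_maps(tile, smooth_sigma = 0)
  cands <- candidates(maps, prob_threshold = 0.5, stride = 2)
  expect_gt(length(cands), 0)
  expect_true(all(diff(cands$scores) <= 0))
  expect_true(all(cands$centers %% 2 == 0))
  # all candidate centres lie inside the disc
  d2 <- (cands$centers[, 1] - 32)^2 + (cands$centers[, 2] - 32)^2
  expect_true(all(d2 <= 8.5^2))
  # threshold 1 on a map with max prob 1 keeps only prob-1 pixels;
  # threshold above max gives empty set
  expect_error(candidates(maps, prob_threshold = 1.5), "prob_threshold")
  few <- candidates(maps, prob_threshold = 0.999999)
  expect_true(all(few$scores >= 0.999999))
})

test_that("nms equals the brute-force reference on random candidates", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(c(20, 60, 150), 1)
    centers <- cbind(runif(n, 0, 80), runif(n, 0, 80))
    radii <- matrix(runif(n * 16, 2, 8), n, 16)
    scores <- sort(runif(n), decreasing = TRUE)
    cands <- nucleograde:::new_nucleus_set(centers, radii, scores)
    for (thr in c(0.3, 0.5)) {
      kept <- nms(cands, thr)
      ref <- nms_bruteforce(cands, thr)
      expect_equal(kept$scores, cands$scores[ref])
      expect_equal(kept$centers, cands$centers[ref, , drop = FALSE])
    }
  }
})

test_that("nms keeps the top-scoring duplicate and all disjoint", {
  centers <- rbind(c(10, 10), c(10, 10), c(50, 50))
  radii <- matrix(5, 3, 8)
  cands <- nucleograde:::new_nucleus_set(centers, radii, c(0.9, 0.8, 0.7))
  out <- nms(cands, 0.5)
  expect_equal(out$scores, c(0.9, 0.7))
  expect_error(nms(cands, 1.5), "iou_threshold")
  unsorted <- nucleograde:::new_nucleus_set(centers, radii,
                                            c(0.5, 0.8, 0.7))
  expect_error(nms(unsorted, 0.5), "sorted")
})

test_that("rasterize follows pixel-centre inclusion and score priority", {
  # empty set -> all-zero mask
  empty <- nucleograde:::new_nucleus_set(matrix(0, 0, 2),
                                         matrix(0, 0, 8), numeric(0))
  expect_true(all(rasterize(empty, c(20, 20)) == 0))
  # one square of side 10 centred at (15, 15): 100 px +- boundary rule
  sq_r <- rep(c(5 * sqrt(2), 5), 2)[c(1, 2, 1, 2, 1, 2, 1, 2)]
  inst <- nucleograde:::new_nucleus_set(
    matrix(c(15, 15), 1), matrix(5 / cos(pi / 8), 1, 8), 1)
  m <- rasterize(inst, c(30, 30))
  area_poly <- nucleograde:::cpp_polygon_area(
    polygon_from_rays(c(15, 15), rep(5 / cos(pi / 8), 8)))
  expect_lt(abs(sum(m > 0) - area_poly), 0.15 * area_poly)
  # overlapping instances: each pixel single-labelled, highest score wins
  two <- nucleograde:::new_nucleus_set(rbind(c(10, 10), c(14, 10)),
                                       matrix(6, 2, 8), c(0.9, 0.8))
  m2 <- rasterize(two, c(25, 25))
  expect_setequal(unique(as.vector(m2)), c(0L, 1L, 2L))
  expect_equal(m2[11, 11], 1L)  # centre of the higher-score instance
  # fully outside instance dropped with warning
  out <- nucleograde:::new_nucleus_set(matrix(c(100, 100), 1),
                                       matrix(3, 1, 8), 1)
  expect_warning(m3 <- rasterize(out, c(20, 20)), "outside")
  expect_true(all(m3 == 0))
})

test_that("segmentation is deterministic and recovers planted nuclei", {
  tile <- small_tile(n_cells = 120, seed = 5)
  s1 <- segment_tile(tile$image)
  s2 <- segment_tile(tile$image)
  expect_identical(s1$mask, s2$mask)
  ms <- match_instances(tile$truth$instance_mask, s1$mask)
  expect_gte(ms$matched / ms$n_true, 0.95)
  expect_lte(ms$fp / ms$n_pred, 0.05)
})
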