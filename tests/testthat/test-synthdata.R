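test_that("largest-remainder apportionment is exact and deterministic", {
  expect_identical(largest_remainder(c(0.45, 0.15, 0.05, 0.35), 400),
                   c(180L, 60L, 20L, 140L))
  # ties broken by position order
  expect_identical(largest_remainder(c(0.5, 0.25, 0.25), 2),
                   c(1L, 1L, 0L))
  # property: counts sum to n and are within 1 of the quota
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    mix <- runif(k); mix <- mix / sum(mix)
    n <- sample(1:500, 1)
    cnt <- largest_remainder(mix, n)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - mix * n) < 1))
  }
  expect_error(largest_remainder(c(0.4, 0.4), 10), "sum to 1")
})

test_that("make_tile plants exact class counts and is bit-reproducible", {
  spec <- tile_spec(width_px = 600, height_px = 600, n_cells = 400,
                    class_mix = c(G1 = 0.5, G2 = 0.15, G3 = 0.05,
                                  Other = 0.3), seed = 7)
  a <- make_tile(spec)
  expect_equal(sum(a$truth$labels == "G3"), 20)
  expect_equal(length(a$truth$labels), 400)
  b <- make_tile(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$instance_mask, b$truth$instance_mask)
  # different seed gives a different layout
  c_ <- make_tile(tile_spec(width_px = 600, height_px = 600,
                            n_cells = 400, seed = 8))
  expect_false(identical(a$truth$centers_um, c_$truth$centers_um))
})

test_that("ground-truth mask ids are contiguous and instances disjoint", {
  tile <- small_tile(n_cells = 80, seed = 11)
  m <- tile$truth$instance_mask
  ids <- sort(unique(as.vector(m)))
  expect_identical(ids, 0:80)
  # non-overlap is structural: every labelled pixel has exactly one id,
  # and planted polygons pairwise IoU must be 0
  polys <- tile$truth$polygons
  set.seed(1)
  for (k in 1:30) {
    ij <- sample(80, 2)
    expect_equal(polygon_iou(polys[[ij[1]]], polys[[ij[2]]]), 0)
  }
})

test_that("overdense packing fails with an informative error", {
  spec <- tile_spec(width_px = 200, height_px = 200, n_cells = 2000,
                    seed = 1)
  expect_error(make_tile(spec), "packing failed")
})

test_that("pattern presets match the four printed %G3 distributions", {
  pp <- pattern_presets()
  expect_equal(pp$monomorphic$pct_mean, 5.24)
  expect_equal(pp$monomorphic$pct_sd, 3.55)
  expect_equal(pp$pluralistic$pct_mean, 18.45)
  expect_equal(pp$nucleolar$pct_mean, 28.29)
  expect_equal(pp$nucleolar$pct_sd, 10.04)
  expect_equal(pp$dystrophic$pct_mean, 8.56)
  # degenerate sd: draw equals the mean exactly
  set.seed(1)
  expect_equal(pattern_params("monomorphic", sd_scale = 0)$pct_g3, 5.24)
  expect_error(pattern_params("lobular"), "unknown pattern")
})

test_that("nucleolar pattern draws average to the printed mean", {
  set.seed(123)
  draws <- replicate(400, pattern_params("nucleolar")$pct_g3)
  # truncation at 0 lifts the mean of N(28.29, 10.04) by < 0.03, so the
  # Monte-Carlo band around 28.29 dominates
  expect_lt(abs(mean(draws) - 28.29), 3 * 10.04 / sqrt(400))
})

test_that("dystrophic pattern tiles stay under 5000 cells/mm^2", {
  tile <- make_pattern_tile("dystrophic", seed = 5, area_mm2 = 0.04)
  dens <- length(tile$truth$labels) / 0.04
  expect_lt(dens, 5000)
})

test_that("make_pattern_tile is seeded and carries the planted fraction", {
  a <- make_pattern_tile("monomorphic", seed = 3, area_mm2 = 0.01)
  b <- make_pattern_tile("monomorphic", seed = 3, area_mm2 = 0.01)
  expect_identical(a$image, b$image)
  expect_identical(attr(a, "planted_pct_g3"), attr(b, "planted_pct_g3"))
  g3 <- mean(a$truth$labels == "G3") * 100
  # realised fraction equals the planted one up to apportionment rounding
  expect_lt(abs(g3 - attr(a, "planted_pct_g3")),
            100 / length(a$truth$labels) + 1e-9)
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(censor_time = 0), "censor_time")
  expect_error(cohort_spec(quadrant_mix = c(0.5, 0.5, 0.2, 0)),
               "summing to 1")
  expect_error(cohort_spec(hazard_per_quadrant = c(0.1, -1, 0.1, 0.1)),
               "positive")
})

test_that("make_cohort draws quadrant-consistent records", {
  spec <- cohort_spec(n_samples = 80, seed = 21)
  co <- make_cohort(spec)
  expect_equal(nrow(co), 80)
  expect_true(all(co$time_days > 0))
  expect_true(all(co$event %in% 0:1))
  # drawn densities always agree with the assigned quadrant
  expect_identical(as.character(co$quadrant),
                   as.character(assign_quadrant(co$dens_g3,
                                                co$dens_other)))
  expect_identical(co, make_cohort(spec))
})

test_that("cohort survival medians recover ln2/lambda", {
  # no censoring, large n: KM median of exponential draws ~ ln2/lambda
  spec <- cohort_spec(n_samples = 4000,
                      quadrant_mix = c(1, 0, 0, 0),
                      hazard_per_quadrant = rep(log(2) / 804, 4),
                      censor_time = 1e7, seed = 31)
  co <- make_cohort(spec)
  expect_true(all(co$quadrant == "G3+/O-"))
  med <- km_median(km_fit(co$time_days, co$event))
  expect_lt(abs(med - 804) / 804, 0.05)
})

test_that("quadrant mix round-trips through assign_quadrant", {
  for (q in 1:4) {
    mix <- rep(0, 4); mix[q] <- 1
    co <- make_cohort(cohort_spec(n_samples = 25, quadrant_mix = mix,
                                  seed = 40 + q))
    expect_true(all(assign_quadrant(co$dens_g3, co$dens_other) ==
                      c("G3+/O-", "G3+/O+", "G3-/O-", "G3-/O+")[q]))
  }
})

test_that("make_grade_cohort is grade-structured and reproducible", {
  gc_df <- make_grade_cohort(seed = 9)
  expect_identical(gc_df, make_grade_cohort(seed = 9))
  expect_setequal(unique(gc_df$grade), 1:4)
  expect_true(all(gc_df$pct_g3 >= 0 & gc_df$pct_g3 <= 100))
  expect_equal(gc_df$dens_g3 + gc_df$dens_other, gc_df$n_total)
})
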