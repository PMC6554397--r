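mk <- function(nx, ny) matrix(FALSE, nx, ny)

test_that("surface coverage algebra", {
  a <- mk(100, 100); b <- mk(100, 100)
  expect_identical(surface_coverage(a, b), 0)
  expect_identical(surface_coverage(!a, !b), 1)
  a[1:50, ] <- TRUE          # left half
  b[, 1:50] <- TRUE          # top half
  expect_equal(surface_coverage(a, b), 0.75)
  expect_equal(surface_coverage(a, b), surface_coverage(b, a))
  expect_equal(surface_coverage(a, a), surface_coverage(a, mk(100, 100)))
  expect_error(surface_coverage(a, mk(50, 100)), "mismatch")
})

test_that("8-connected labelling agrees with exhaustive flood fill", {
  m <- mk(9, 9); m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch
  expect_identical(max(label8(m)), 1L)
  set.seed(210)
  for (i in 1:12) {
    m <- matrix(runif(30 * 30) < 0.25, 30, 30)
    expect_identical(max(label8(m)), brute_n_components8(m))
  }
})

test_that("the 15-pixel minimum-area rule is exact at the boundary", {
  r <- matrix(0.05, 128, 128)
  r[10:16, 10:11] <- 1       # 14 px: removed
  r[40:44, 40:42] <- 1       # 15 px: retained
  s <- segment_channel(r)
  expect_identical(length(s$areas), 1L)
  expect_identical(s$areas, 15L)
  expect_warning(s0 <- segment_channel(matrix(0.3, 64, 64)), "aberrant")
  expect_identical(length(s0$areas), 0L)
})

test_that("segmentation recovers the single-cell fixture within 30%", {
  f <- make_fixture("single_cell")
  s <- segment_channel(f$ch1)
  expect_identical(length(s$areas), 1L)
  expect_lt(abs(s$areas / 40 - 1), 0.3)
})

test_that("closing matches brute-force morphology and bridges 6 px gaps", {
  g6 <- make_fixture("two_squares_gap6")
  g20 <- make_fixture("two_squares_gap20")
  for (m in list(g6$truth1, g20$truth1)) {
    expect_identical(close_mask(m, 5), brute_closing(m, 5))
  }
  blank2 <- mk(120, 80)
  expect_identical(colony_areas(g6$truth1, blank2, 1)$n_colonies, 1L)
  expect_identical(colony_areas(g20$truth1, blank2, 1)$n_colonies, 2L)
})

test_that("colony areas: filters, closing and the printed pixel scale", {
  a <- mk(80, 80); a[10:29, 10:29] <- TRUE    # 400 px, kept
  b <- mk(80, 80); b[50:59, 50:59] <- TRUE    # 100 px, filtered out
  cs <- colony_areas(a, b, pixel_um = 0.1791)
  expect_identical(cs$n_colonies, 1L)
  expect_equal(cs$median_um2, 400 * 0.1791^2, tolerance = 1e-12)
  expect_false(cs$gated)
  # close-then-filter alternative ordering is available
  cs2 <- colony_areas(a, b, 0.1791, filter_then_close = FALSE)
  expect_identical(cs2$n_colonies, 1L)
})

test_that("near-saturated images are excluded by the coverage gate", {
  f <- make_fixture("near_saturated")
  cs <- colony_areas(f$truth1, f$truth2, f$pixel_um)
  expect_true(cs$gated)
  expect_gt(cs$coverage, 0.8)
  expect_null(cs$areas_um2)
  expect_true(is.na(cs$median_um2))
})

test_that("cross-lineage mixing distances are Euclidean and pooled", {
  # 3-4-5 triangle: centroids (10,10) and (13,14), 1 um pixels
  a <- mk(40, 40); a[10:11, 10:11] <- TRUE    # centroid (10, 10)
  b <- mk(40, 40); b[13:14, 14:15] <- TRUE    # centroid (13, 14)
  mx <- cross_lineage_mixing(a, b, pixel_um = 1, close_radius = 0)
  expect_identical(mx$n, 2L)
  expect_equal(mx$mean_um, 5)
  expect_equal(mx$distances_um, c(5, 5))

  cb <- make_fixture("checkerboard_mixed")
  mcb <- cross_lineage_mixing(cb$truth1, cb$truth2, cb$pixel_um)
  expect_equal(mcb$mean_um, 16 * cb$pixel_um, tolerance = 1e-12)
  expect_identical(mcb$n, 64L)

  sg <- make_fixture("segregated_halves")
  msg <- cross_lineage_mixing(sg$truth1, sg$truth2, sg$pixel_um)
  expect_equal(msg$mean_um, 70 * sg$pixel_um, tolerance = 1e-12)
  expect_gte(msg$mean_um, 30 * sg$pixel_um)   # at least the edge gap

  und <- cross_lineage_mixing(a, mk(40, 40), 1)
  expect_false(und$defined)
  expect_true(is.na(und$mean_um))
})

test_that("measurements are invariant to joint translation and rotation", {
  a <- mk(120, 120); a[20:39, 20:34] <- TRUE; a[70:91, 60:75] <- TRUE
  b <- mk(120, 120); b[50:69, 80:94] <- TRUE
  shift <- function(m, dx, dy) {
    out <- mk(nrow(m), ncol(m))
    out[(1 + dx):nrow(m), (1 + dy):ncol(m)] <-
      m[1:(nrow(m) - dx), 1:(ncol(m) - dy)]
    out
  }
  rot <- function(m) t(m)[ncol(m):1, ]
  base_c <- colony_areas(a, b, 0.2)
  base_m <- cross_lineage_mixing(a, b, 0.2)
  tr_c <- colony_areas(shift(a, 7, 5), shift(b, 7, 5), 0.2)
  tr_m <- cross_lineage_mixing(shift(a, 7, 5), shift(b, 7, 5), 0.2)
  ro_c <- colony_areas(rot(a), rot(b), 0.2)
  ro_m <- cross_lineage_mixing(rot(a), rot(b), 0.2)
  expect_equal(sort(tr_c$areas_um2), sort(base_c$areas_um2))
  expect_equal(sort(ro_c$areas_um2), sort(base_c$areas_um2))
  expect_equal(tr_m$mean_um, base_m$mean_um, tolerance = 1e-12)
  expect_equal(ro_m$mean_um, base_m$mean_um, tolerance = 1e-12)
})

test_that("attachment events require three persistent frames in place", {
  obj_at <- function(x, y) data.frame(x = x, y = y)
  none <- data.frame(x = numeric(0), y = numeric(0))
  # present for two frames only: no event
  fr <- c(rep(list(none), 4), rep(list(obj_at(10, 10)), 2), rep(list(none), 2))
  expect_length(detect_attachment_events(fr, 1:8), 0)
  # three frames within tolerance: one event at the first frame of the run
  fr3 <- c(rep(list(none), 4), rep(list(obj_at(10, 10)), 3), list(none))
  expect_equal(detect_attachment_events(fr3, 1:8), 5)
  # a long run is still a single event
  fr8 <- rep(list(obj_at(3, 3)), 8)
  expect_equal(detect_attachment_events(fr8, 1:8), 1)
  # drifting farther than the tolerance never persists
  drift <- lapply(1:8, function(i) obj_at(10 * i, 3))
  expect_length(detect_attachment_events(drift, 1:8, eps_px = 3), 0)
  # two simultaneous persistent objects are two events
  two <- rep(list(data.frame(x = c(5, 30), y = c(5, 30))), 5)
  expect_length(detect_attachment_events(two, 1:5), 2)
  expect_error(detect_attachment_events(fr3, c(1:7, 10)), "non-uniform")
})

test_that("attachment rate: exact slope, empty flag, Poisson recovery", {
  r <- attachment_rate(rep(1:60, each = 2), 0:60)
  expect_equal(r$rate, 2, tolerance = 1e-9)
  z <- attachment_rate(numeric(0), 0:60)
  expect_identical(z$rate, 0)
  expect_true(z$no_events)
  set.seed(220)
  ev <- cumsum(rexp(600, rate = 0.5))
  ev <- ev[ev <= 600]
  pr <- attachment_rate(ev, seq(0, 600, by = 1))
  expect_lt(abs(pr$rate - 0.5), 3 * sqrt(0.5 / 600))
})

test_that("attachment probability follows the flux normalization", {
  # r = 9 cells/s, Q = 1 ul/s, C = 4.5e4 cells/ul -> 2e-4
  ap <- attachment_probability(9, Q = 1e-9, C = 4.5e13,
                               geometry = default_geometry())
  expect_equal(ap$p_att, 2e-4, tolerance = 1e-12)
  expect_equal(ap$flux, 1e-9 * 4.5e13 / default_geometry()$area)
  expect_identical(attachment_probability(0, 1e-9, 4.5e13)$p_att, 0)
  half <- attachment_probability(9, 1e-9, 9e13)$p_att
  expect_equal(half, ap$p_att / 2)
  expect_error(attachment_probability(10, 1e-9, 1e9), "inconsistent")
})

test_that("image-derived measurements recover ground truth on renders", {
  cfg <- replica_config(n_seeds = 1)
  row <- flowcolonize:::measure_condition(cfg, 2, seed = 11)
  expect_lt(abs(row$coverage / row$truth_coverage - 1), 0.10)
  expect_lt(abs(row$mixing_mean_um / row$mixing_truth_mean_um - 1), 0.15)
})
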