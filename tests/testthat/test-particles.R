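test_that("subtract_core clears exactly the pixels inside or on the ellipse", {
  ell <- ellipse(60, 60, 30, 18, pi / 7)
  interior <- ellipse_mask(120, 120, 60, 60, 30, 18, pi / 7)
  expect_false(any(subtract_core(interior, ell)))
  blob <- disk_mask(120, 120, 105, 20, 6)
  expect_identical(subtract_core(blob, ell), blob)
  # straddling blob: per-pixel oracle with the explicit quadratic form
  strad <- disk_mask(120, 120, 60 + 30 * cos(pi / 7), 60 + 30 * sin(pi / 7), 8)
  out <- subtract_core(strad, ell)
  xs <- rep(seq_len(120), each = 120) - 60
  ys <- rep(seq_len(120), times = 120) - 60
  u <- cos(pi / 7) * xs + sin(pi / 7) * ys
  v <- -sin(pi / 7) * xs + cos(pi / 7) * ys
  outside <- matrix((u / 30)^2 + (v / 18)^2 > 1 + 1e-12, 120, 120)
  expect_identical(out, strad & outside)
})

test_that("split_particles labels disjoint blobs without spurious splits", {
  m <- disk_mask(200, 200, 50, 50, 20) | disk_mask(200, 200, 150, 150, 15)
  lab <- split_particles(m)
  expect_equal(max(lab), 2L)
  expect_equal(max(split_particles(disk_mask(200, 200, 100, 100, 40))), 1L)
  expect_equal(max(split_particles(matrix(FALSE, 10, 10))), 0L)
})

test_that("overlapping disks split along the mid-perpendicular", {
  m <- disk_mask(200, 260, 100, 100, 40) | disk_mask(200, 260, 160, 100, 40)
  lab <- split_particles(m, h_min = 5)
  expect_equal(max(lab), 2L)
  expect_identical(lab > 0L, m)           # foreground preserved
  for (l in 1:2) {
    xs <- which(lab == l, arr.ind = TRUE)[, 2L]
    side <- if (mean(xs) < 130) expect_lt(max(xs), 130 + 3)
            else expect_gt(min(xs), 130 - 3)
  }
})

test_that("split_particles conserves foreground and never merges components", {
  sc <- generate_scene(small_scene_params(seed = 9))
  inv <- subtract_core(sc$truth_labels > 0L | ellipse_mask(
    256, 256, 128, 128, 45, 30, pi / 6), sc$truth_core)
  lab <- split_particles(inv)
  expect_identical(lab > 0L, inv)
  comp <- label_components(inv)
  # every 8-connected component maps to >= 1 watershed label, never shared
  for (cid in seq_len(max(comp))) {
    expect_false(any(lab[comp == cid] %in% lab[comp != cid & comp > 0]))
  }
})

test_that("size filter is strict, idempotent and monotone", {
  lab <- matrix(0L, 40, 40)
  lab[2, 1:5] <- 1L                        # 5 px
  lab[10, 1:10] <- 2L                      # 10 px
  lab[20, 1:11] <- 3L                      # 11 px
  out <- filter_particles(lab, min_area = 10)
  expect_equal(max(out), 1L)
  expect_equal(sum(out > 0L), 11L)
  expect_true(all(out[20, 1:11] == 1L))
  expect_identical(filter_particles(out, 10), out)
  expect_equal(max(filter_particles(lab, 0)), 3L)
  expect_equal(max(filter_particles(matrix(0L, 4, 4), 10)), 0L)
  # monotone: raising the threshold never adds particles
  ns <- vapply(c(0, 4, 9, 10, 11), function(t)
    max(filter_particles(lab, t)), integer(1L))
  expect_true(all(diff(ns) <= 0))
})

test_that("measure_particles reports exact areas, centroids and distances", {
  ell <- ellipse(100, 100, 50, 50)
  lab <- matrix(0L, 220, 220)
  lab[180:184, 100:104] <- 1L              # 5x5 square, centroid (102, 182)
  tab <- measure_particles(lab, ell, pixel_size = 0.5)
  expect_equal(tab$area_px2, 25)
  expect_equal(tab$area_um2, 25 * 0.25)
  expect_equal(tab$centroid_x, 102)
  expect_equal(tab$centroid_y, 182)
  d_closed <- abs(sqrt((102 - 100)^2 + (182 - 100)^2) - 50)
  expect_equal(tab$distance_px, d_closed, tolerance = 1e-6)
  expect_equal(tab$distance_um, tab$distance_px * 0.5)
  # uncalibrated: um columns NA
  tab_px <- measure_particles(lab, ell)
  expect_true(is.na(tab_px$area_um2) && is.na(tab_px$distance_um))
})

test_that("nearest_pixel distance never exceeds centroid distance", {
  sc <- generate_scene(small_scene_params(seed = 13))
  lab <- sc$truth_labels
  tc <- measure_particles(lab, sc$truth_core, distance_mode = "centroid")
  tn <- measure_particles(lab, sc$truth_core, distance_mode = "nearest_pixel")
  expect_equal(tn$label, tc$label)
  expect_true(all(tn$distance_px <= tc$distance_px + 1e-9))
  # and nearest_pixel equals the exhaustive per-pixel minimum
  for (l in tc$label[1:3]) {
    px <- which(lab == l, arr.ind = TRUE)
    expect_equal(tn$distance_px[l],
                 min(edge_distances(px[, 2], px[, 1], sc$truth_core)),
                 tolerance = 1e-9)
  }
})

test_that("label partition conserves the post-subtraction foreground", {
  sc <- generate_scene(small_scene_params(seed = 29, noise_sd = 20))
  rec <- recover_particles(sc, min_area = 0, h_min = 5)
  inv <- subtract_core(rec$mask, sc$truth_core)
  expect_equal(sum(rec$table$area_px2), sum(inv))
})
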