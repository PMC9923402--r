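mk_table <- function(areas, dists, pixel_size = NULL) {
  data.frame(label = seq_along(areas), area_px2 = areas,
             area_um2 = if (is.null(pixel_size)) rep(NA_real_, length(areas))
                        else areas * pixel_size^2,
             centroid_x = rep(0, length(areas)),
             centroid_y = rep(0, length(areas)), distance_px = dists,
             distance_um = if (is.null(pixel_size)) rep(NA_real_, length(dists))
                           else dists * pixel_size)
}

test_that("summarize_invasion computes the three invasion statistics", {
  m <- summarize_invasion(mk_table(c(20, 30), c(5, 15)))
  expect_equal(m$invasive_area_px2, 50)
  expect_equal(m$mean_distance_px, 10)
  expect_equal(m$max_distance_px, 15)
  expect_equal(m$n_particles, 2L)
  # single particle: mean == max exactly
  m1 <- summarize_invasion(mk_table(12, 7.3))
  expect_identical(m1$mean_distance_px, m1$max_distance_px)
  # empty table
  m0 <- summarize_invasion(mk_table(numeric(0), numeric(0)))
  expect_equal(m0$invasive_area_px2, 0)
  expect_equal(m0$n_particles, 0L)
  expect_true(is.na(m0$mean_distance_px) && is.na(m0$max_distance_px))
  # calibrated units carried through
  mc <- summarize_invasion(mk_table(c(20, 30), c(5, 15), pixel_size = 0.5))
  expect_equal(mc$invasive_area_um2, 50 * 0.25)
  expect_equal(mc$max_distance_um, 7.5)
})

test_that("invasive area is additive over disjoint scene parts", {
  t1 <- mk_table(c(20, 14), c(3, 9))
  t2 <- mk_table(c(40), c(21))
  joint <- rbind(t1, t2)
  joint$label <- seq_len(nrow(joint))
  m <- summarize_invasion(joint)
  expect_equal(m$invasive_area_px2,
               summarize_invasion(t1)$invasive_area_px2 +
                 summarize_invasion(t2)$invasive_area_px2)
  expect_equal(m$max_distance_px,
               max(summarize_invasion(t1)$max_distance_px,
                   summarize_invasion(t2)$max_distance_px))
})

test_that("summary statistics on a synthetic scene match ground truth", {
  sc <- generate_scene(small_scene_params(n_single_cells = 12, seed = 3))
  rec <- recover_particles(sc)
  m <- summarize_invasion(rec$table)
  truth <- summarize_invasion(sc$truth_table)
  expect_equal(m$invasive_area_px2, truth$invasive_area_px2)
  expect_equal(m$n_particles, truth$n_particles)
  expect_lt(abs(m$mean_distance_px - truth$mean_distance_px), 1)
  expect_lt(abs(m$max_distance_px - truth$max_distance_px), 1)
})

test_that("pct_within_slice handles lines, symmetry and monotonicity", {
  sph <- disk_mask(200, 100, 50, 120, 30)
  expect_equal(pct_within_slice(sph, surface_line = 50), 100)
  expect_equal(pct_within_slice(sph, surface_line = 120), 50, tolerance = 2)
  lines <- seq(180, 60, by = -10)
  pcts <- vapply(lines, function(L) pct_within_slice(sph, surface_line = L),
                 numeric(1L))
  expect_true(all(diff(pcts) >= 0))
  expect_error(pct_within_slice(matrix(FALSE, 5, 5), surface_line = 1),
               "no spheroid")
  expect_error(pct_within_slice(sph), "exactly one")
  expect_error(pct_within_slice(sph, surface_line = 1,
                                tissue_mask = sph), "exactly one")
})

test_that("the slice surface is recovered from a tissue mask", {
  tissue <- matrix(FALSE, 200, 100)
  tissue[77:200, ] <- TRUE
  tissue[77, c(3, 40)] <- FALSE        # ragged top should not move the median
  sph <- disk_mask(200, 100, 50, 120, 30)
  expect_equal(pct_within_slice(sph, tissue_mask = tissue),
               pct_within_slice(sph, surface_line = 77))
})

test_that("aggregate_replicates averages within brains then across brains", {
  df <- data.frame(
    image_id = c("i1", "i2", "i3"),
    brain_id = c("b1", "b1", "b2"),
    invasive_area_px2 = c(100, 200, 250),
    mean_distance_px = c(4, 6, 10))
  agg <- aggregate_replicates(df)
  b1 <- agg$per_brain[agg$per_brain$brain_id == "b1", ]
  expect_equal(b1$invasive_area_px2, 150)
  expect_equal(b1$n_images, 2L)
  g <- agg$group[agg$group$metric == "invasive_area_px2", ]
  expect_equal(g$mean, 200)
  expect_equal(g$sd, sd(c(150, 250)))
  expect_equal(g$n_brains, 2L)
  # permutation invariance
  agg2 <- aggregate_replicates(df[c(3, 1, 2), ])
  expect_equal(agg2$per_brain, agg$per_brain)
  expect_equal(agg2$group, agg$group)
})
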