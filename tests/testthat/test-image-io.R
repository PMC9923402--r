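test_that("calibrated_image and channel_stack enforce their invariants", {
  expect_error(calibrated_image(matrix(-1, 2, 2)), ">= 0")
  expect_error(calibrated_image(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  expect_error(calibrated_image(matrix(1, 2, 2), pixel_size = 0), "> 0")
  a <- calibrated_image(matrix(1, 4, 4), 0.5, "GFP")
  b <- calibrated_image(matrix(2, 4, 4), 0.5, "GFAP")
  expect_s3_class(channel_stack(a, b), "channel_stack")
  expect_error(channel_stack(a, a), "unique")
  expect_error(
    channel_stack(a, calibrated_image(matrix(1, 3, 3), 0.5, "GFAP")),
    "dimensions")
  expect_error(
    channel_stack(a, calibrated_image(matrix(1, 4, 4), 0.7, "GFAP")),
    "calibration")
})

test_that("TIFF write/read round-trips pixels, calibration and names", {
  set.seed(11)
  a <- calibrated_image(matrix(sample(0:65535, 64 * 64, TRUE), 64, 64),
                        0.5, "GFP")
  b <- calibrated_image(matrix(sample(0:65535, 64 * 64, TRUE), 64, 64),
                        0.5, "GFAP")
  f <- file.path(withr::local_tempdir(), "two_channel.tif")
  write_stack(channel_stack(a, b), f)
  st <- read_stack(f)
  expect_length(st, 2L)
  expect_identical(names(st), c("GFP", "GFAP"))
  expect_equal(st$GFP$pixel_size, 0.5)
  expect_identical(st$GFP$pixels, a$pixels)
  expect_identical(st$GFAP$pixels, b$pixels)
})

test_that("pixel-size override beats file metadata; absent metadata means NULL", {
  d <- withr::local_tempdir()
  img <- calibrated_image(matrix(0:255, 16, 16), channel = "GFP")
  f <- file.path(d, "mono.tif")
  write_stack(channel_stack(img), f, bits = 8L)
  expect_null(read_stack(f)$GFP$pixel_size)
  expect_equal(read_stack(f, pixel_size = 1.0)$GFP$pixel_size, 1.0)
  # override also beats a sidecar that does carry calibration
  img2 <- calibrated_image(matrix(0:255, 16, 16), 0.5, "GFP")
  f2 <- file.path(d, "cal.tif")
  write_stack(channel_stack(img2), f2, bits = 8L)
  expect_equal(read_stack(f2)$GFP$pixel_size, 0.5)
  expect_equal(read_stack(f2, pixel_size = 2)$GFP$pixel_size, 2)
})

test_that("read_stack rejects missing and unsupported files", {
  expect_error(read_stack("no/such/file.tif"), "cannot read")
  d <- withr::local_tempdir()
  f <- file.path(d, "five.tif")
  planes <- replicate(5, matrix(runif(16), 4, 4), simplify = FALSE)
  tiff::writeTIFF(planes, f)
  expect_error(read_stack(f), "at most 4")
  frgb <- file.path(d, "rgb.tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), frgb)
  expect_error(read_stack(frgb), "non-2-D")
})

test_that("select_channel returns channels verbatim and fails informatively", {
  a <- calibrated_image(matrix(7, 4, 4), channel = "GFP")
  b <- calibrated_image(matrix(9, 4, 4), channel = "GFAP")
  st <- channel_stack(a, b)
  expect_identical(select_channel(st, "GFP"), a)
  expect_identical(select_channel(channel_stack(a), "GFP"), a)
  expect_identical(select_channel(st, index = 2L), b)
  expect_error(select_channel(st, "DAPI"), "GFP, GFAP")
})

test_that("to_8bit maps linearly with round-half-up and degenerate rule", {
  const <- calibrated_image(matrix(500, 3, 3), 0.5)
  expect_true(all(to_8bit(const)$pixels == 0))
  expect_equal(to_8bit(const)$pixel_size, 0.5)
  img <- calibrated_image(matrix(c(0, 500, 1000, 0), 2, 2))
  out <- to_8bit(img)$pixels
  expect_equal(out[2, 1], 128)  # 500/1000 * 255 = 127.5, rounds half up
  expect_equal(out[1, 2], 255)
  full <- calibrated_image(matrix(c(0, 100, 255, 17), 2, 2))
  expect_identical(to_8bit(full)$pixels, full$pixels)
})

test_that("to_8bit preserves pixel ordering (monotone)", {
  set.seed(3)
  for (i in 1:5) {
    v <- runif(200, 0, 4096)
    out <- as.vector(to_8bit(calibrated_image(matrix(v, 10, 20)))$pixels)
    expect_true(all(diff(out[order(v)]) >= 0))
  }
})

test_that("write_results produces ordered CSV plus metrics JSON and round-trips", {
  d <- withr::local_tempdir()
  ell <- ellipse(50, 50, 20, 10)
  lab <- matrix(0L, 100, 100)
  lab[10:12, 10:14] <- 1L; lab[80:85, 80:82] <- 2L; lab[5, 90:99] <- 3L
  tab <- measure_particles(lab, ell, pixel_size = 0.5)
  mets <- summarize_invasion(tab)
  p <- file.path(d, "res.csv")
  out <- write_results(tab, mets, p)
  re <- read.csv(p)
  expect_equal(nrow(re), 3L)
  expect_equal(signif(re$distance_px, 6), signif(tab$distance_px, 6))
  expect_equal(signif(re$area_um2, 6), signif(tab$area_um2, 6))
  j <- jsonlite::read_json(out$json, simplifyVector = TRUE)
  expect_equal(j$n_particles, 3L)
  # empty table
  p0 <- file.path(d, "empty.csv")
  write_results(measure_particles(matrix(0L, 5, 5), ell),
                summarize_invasion(measure_particles(matrix(0L, 5, 5), ell)), p0)
  expect_equal(nrow(read.csv(p0)), 0L)
  j0 <- jsonlite::read_json(paste0(tools::file_path_sans_ext(p0), ".json"),
                            simplifyVector = TRUE)
  expect_equal(j0$n_particles, 0L)
})
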