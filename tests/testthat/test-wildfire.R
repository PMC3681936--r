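test_that("wildfire fill matches the brute-force dilation oracle", {
  set.seed(101)
  cfg <- segmentation_config()
  for (rep in 1:60) {
    nr <- sample(24:96, 1); nc <- sample(24:96, 1)
    img <- random_blob_image(nr, nc, n_blobs = sample(2:6, 1))
    seed <- c(sample(nr, 1), sample(nc, 1))
    tol <- sample(c(5, 20, 50), 1)
    got <- wildfire_fill(img, seed,
                         segmentation_config(brightness_tol = tol))$mask
    want <- oracle_flood_fill(img, seed, tol)
    expect_identical(unname(got), unname(want))
  }
})

test_that("fill respects the seed-relative brightness criterion", {
  img <- ring_image()
  cen <- c(21, 21)
  reg <- wildfire_fill(img, cen)
  # region is exactly the lumen pixel set of the closed ring
  d <- sqrt((row(img) - 21)^2 + (col(img) - 21)^2)
  expect_identical(unname(reg$mask), unname(d <= 8))
  # no accepted pixel violates the criterion
  expect_true(all(abs(img[reg$mask] - img[21, 21]) <= 20))
  # uniform image: everything joins the region
  uni <- matrix(100, 20, 20)
  expect_true(all(wildfire_fill(uni, c(3, 3))$mask))
  # a painted gap leaks the fill into the background
  leaky <- ring_image(gap_deg = c(10, 60))
  reg2 <- wildfire_fill(leaky, cen)
  expect_gt(reg2$area_px, sum(d <= 8) + 100)
  expect_true(reg2$touches_border)
})

test_that("contours track the region boundary and smoothing stays gentle", {
  # perfect digital disk, r = 20 px: smoothed contour area within 2%
  n <- 50
  m <- matrix(0, n, n)
  m[(row(m) - 25.5)^2 + (col(m) - 25.5)^2 <= 400] <- 1
  ct <- region_to_contour(m == 1, segmentation_config(), calibration(1, 1), 1)
  expect_lt(abs(polygon_area(ct) / (pi * 400) - 1), 0.02)
  # window 1 leaves the traced boundary untouched
  ct1 <- region_to_contour(m == 1, segmentation_config(smooth_window = 1),
                           calibration(1, 1), 1)
  ct7 <- region_to_contour(m == 1, segmentation_config(smooth_window = 7),
                           calibration(1, 1), 1)
  expect_false(isTRUE(all.equal(ct1$vertices, ct7$vertices)))
  expect_lt(abs(polygon_area(ct1) / (pi * 400) - 1), 0.02)
  # degenerate 1-pixel region
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_error(region_to_contour(one, segmentation_config(),
                                 calibration(1, 1), 1), "too small")
  # a region touching the image border is flagged open
  half <- matrix(FALSE, 12, 12); half[1:6, 4:8] <- TRUE
  ctb <- region_to_contour(half, segmentation_config(), calibration(1, 1), 1)
  expect_true(ctb$border_open)
})

test_that("manual circles are faithful regular polygons", {
  ct <- manual_circle(c(10, 12), 2, slice_index = 3)
  expect_equal(ct$source, "manual_circle")
  expect_lt(abs(polygon_area(ct) / (pi * 4) - 1), 0.005)
  expect_identical(manual_circle(c(1, 1), 0.5, 1)$vertices,
                   manual_circle(c(1, 1), 0.5, 1)$vertices)
  expect_error(manual_circle(c(0, 0), -1, 1))
})

test_that("propagation completes artifact-free traces from any lumen seed", {
  cf <- phantom_config(n_axons = 1, n_slices = 6, image_size = c(64, 64),
                       diameter_range = c(4, 4), gap_probability = 0,
                       noise_sd = 0, area_fluctuation_cv = 0,
                       trajectory_amplitude = 0.3, seed = 8)
  ph <- generate_phantom(cf)
  s <- truth_seeds(ph)
  for (off in list(c(0, 0), c(2, 0), c(0, -2))) {
    res <- propagate_trace(ph$stack, "axon001",
                           c(s$row_px[1], s$col_px[1]) + off)
    expect_equal(res$trace$status, "complete")
    expect_length(res$trace$contours, 6)
    expect_equal(nrow(res$abortions), 0)
  }
})

test_that("an open boundary aborts the trace at the right slice", {
  slices <- lapply(1:6, function(s)
    if (s == 4) ring_image(gap_deg = c(80, 130)) else ring_image())
  st <- image_stack(slices, calibration(1, 1))
  res <- propagate_trace(st, "axon001", c(21, 21))
  expect_equal(res$trace$status, "aborted")
  expect_equal(nrow(res$abortions), 1)
  expect_equal(res$abortions$slice, 4)
  expect_true(res$abortions$reason %in% c("leak", "area_jump"))
  expect_equal(res$abortions$reason, "leak")
  # with an operator hook the trace continues past the artifact
  res2 <- propagate_trace(st, "axon001", c(21, 21),
                          on_abort = function(ev) c(21, 21))
  expect_equal(res2$trace$status, "complete")
  expect_length(res2$trace$contours, 6)
  expect_equal(nrow(res2$abortions), 1)
  # the gap slice got an operator circle, the rest are grown
  src <- vapply(res2$trace$contours, `[[`, character(1), "source")
  expect_equal(src[4], "manual_circle")
  expect_equal(src[-4], rep("grown", 5))
})

test_that("trace serialization round-trips geometry and the abortion log", {
  cf <- phantom_config(n_axons = 3, n_slices = 4, image_size = c(96, 96),
                       gap_probability = 0, noise_sd = 2, seed = 14)
  ph <- generate_phantom(cf)
  res <- segment_stack(ph$stack, truth_seeds(ph))
  td <- withr::local_tempdir()
  write_traces(res$traces, res$abortions, td)
  back <- read_traces(td)
  expect_setequal(names(back), names(res$traces))
  for (id in names(back)) {
    a0 <- vapply(res$traces[[id]]$contours, polygon_area, numeric(1),
                 check = FALSE)
    a1 <- vapply(back[[id]]$contours, polygon_area, numeric(1), check = FALSE)
    expect_equal(a1, a0, tolerance = 1e-8)
  }
  ab <- read.csv(file.path(td, "abortions.csv"))
  expect_equal(nrow(ab), nrow(res$abortions))
})
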