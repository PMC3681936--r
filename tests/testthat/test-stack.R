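test_that("calibration reproduces the measured nerve reference", {
  cal <- calibrate_from_reference(NULL, 151.6, 151.6 * 2.6, z_step = 0.8)
  expect_equal(cal$xy_scale, 0.3846, tolerance = 1e-4)
  expect_equal(1 / cal$xy_scale, 2.6)
  expect_equal(stack_depth(cal, 625), 500)
  expect_equal(calibrate_from_reference(NULL, 100, 100, z_step = 1)$xy_scale, 1)
  expect_error(calibrate_from_reference(NULL, -1, 100, z_step = 1), "positive")
  # px -> um -> px round trip
  cal2 <- calibration(0.3846, 0.8, shrinkage_factor = 1.1)
  x <- c(0.123, 57.3, 394.16)
  expect_equal(um_to_px(px_to_um(x, cal2), cal2), x, tolerance = 1e-9)
})

test_that("grayscale conversion uses Rec. 601 luminance and is idempotent", {
  white <- array(255, c(4, 4, 3))
  expect_true(all(to_grayscale(white) == 255))
  black <- array(0, c(4, 4, 3))
  expect_true(all(to_grayscale(black) == 0))
  rgb1 <- array(0, c(1, 1, 3))
  rgb1[1, 1, ] <- c(200, 100, 50)
  expect_equal(to_grayscale(rgb1)[1, 1],
               0.299 * 200 + 0.587 * 100 + 0.114 * 50)
  g <- to_grayscale(rgb1)
  expect_identical(to_grayscale(g), g)
})

test_that("crop and rotate90 behave as rigid raster ops", {
  cf <- phantom_config(n_axons = 3, n_slices = 2, image_size = c(96, 96),
                       noise_sd = 0, gap_probability = 0, seed = 4)
  ph <- generate_phantom(cf)
  st <- ph$stack
  r4 <- rotate90_stack(rotate90_stack(rotate90_stack(rotate90_stack(st))))
  expect_equal(r4$slices, st$slices)
  full <- crop_stack(st, c(1, 1, 96, 96))
  expect_identical(full$slices, st$slices)
  expect_error(crop_stack(st, c(90, 90, 20, 20)), "out of bounds")
  # cropping must not change an interior axon's measured area
  seeds <- truth_seeds(ph)
  reg1 <- wildfire_fill(st$slices[[1]], c(seeds$row_px[1], seeds$col_px[1]))
  ct1 <- region_to_contour(reg1, segmentation_config(), st$calibration, 1)
  cr <- crop_stack(st, c(5, 5, 88, 88))
  reg2 <- wildfire_fill(cr$slices[[1]],
                        c(seeds$row_px[1] - 4, seeds$col_px[1] - 4))
  ct2 <- region_to_contour(reg2, segmentation_config(), cr$calibration, 1)
  expect_equal(polygon_area(ct2), polygon_area(ct1), tolerance = 1e-9)
})

test_that("rigid alignment recovers injected per-slice jitter", {
  cf <- phantom_config(n_axons = 25, n_slices = 6, image_size = c(192, 192),
                       misalignment_sd = c(2, 1), noise_sd = 2,
                       gap_probability = 0, area_fluctuation_cv = 0,
                       trajectory_amplitude = 0, seed = 11)
  ph <- generate_phantom(cf)
  res <- align_rigid(ph$stack)
  cmp <- merge(res$transforms, ph$truth$transforms, by = "slice",
               suffixes = c("_est", "_true"))
  terr <- sqrt((cmp$dr_px_est - cmp$dr_px_true)^2 +
               (cmp$dc_px_est - cmp$dc_px_true)^2)
  aerr <- abs(cmp$theta_deg_est - cmp$theta_deg_true)
  expect_lt(max(terr), 0.5)
  expect_lt(max(aerr), 0.25)
  # re-aligning an aligned stack is a no-op within tolerance
  res2 <- align_rigid(res$stack)
  expect_lt(max(abs(c(res2$transforms$dr_px, res2$transforms$dc_px))), 0.5)
  expect_lt(max(abs(res2$transforms$theta_deg)), 0.2)
})

test_that("alignment reports identity on already-aligned stacks and rejects blanks", {
  cf <- phantom_config(n_axons = 15, n_slices = 3, image_size = c(160, 160),
                       misalignment_sd = c(0, 0), noise_sd = 2,
                       gap_probability = 0, area_fluctuation_cv = 0,
                       trajectory_amplitude = 0, seed = 2)
  ph <- generate_phantom(cf)
  res <- align_rigid(ph$stack)
  expect_lt(max(abs(c(res$transforms$dr_px, res$transforms$dc_px))), 0.5)
  expect_lt(max(abs(res$transforms$theta_deg)), 0.2)
  blank <- ph$stack
  blank$slices[[2]][] <- 128
  expect_error(align_rigid(blank), "slice 2")
})

test_that("stack IO round-trips PNG series and multi-page TIFF", {
  cf <- phantom_config(n_axons = 4, n_slices = 3, image_size = c(64, 64),
                       noise_sd = 3, seed = 9)
  ph <- generate_phantom(cf)
  cal <- ph$stack$calibration
  td <- withr::local_tempdir()
  write_stack(ph$stack, file.path(td, "png"))
  back <- read_stack(file.path(td, "png"), cal)
  expect_length(back, 3)
  expect_lt(max(abs(back$slices[[2]] - ph$stack$slices[[2]])), 0.51)
  tp <- file.path(td, "stack.tif")
  write_stack(ph$stack, tp, format = "tiff")
  back2 <- read_stack(tp, cal)
  expect_length(back2, 3)
  expect_lt(max(abs(back2$slices[[3]] - ph$stack$slices[[3]])), 0.51)
})
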