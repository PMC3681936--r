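test_that("lofting conserves volume and the stitching combinatorics", {
  cyl <- make_cylinder(2, 8, n_ring = 64, n_slabs = 10)
  st <- mesh_stats(cyl)
  expect_lt(abs(st$volume / (pi * 4 * 8) - 1), 0.02)
  expect_true(st$watertight)
  expect_equal(st$euler, 2)
  # closed-form counts for k rings of m vertices plus 2 cap apices
  k <- 11; m <- 64
  expect_equal(st$vertex_count, k * m + 2)
  expect_equal(st$face_count, 2 * m * (k - 1) + 2 * m)
  expect_equal(st$face_count, 2 * st$vertex_count - 4)
  # two-slice trace -> closed solid with Euler characteristic 2
  tr <- structure(list(axon_id = "a",
                       contours = list(manual_circle(c(0, 0), 1, 1),
                                       manual_circle(c(0, 0), 1, 2)),
                       status = "complete", start_slice = 1L),
                  class = "axon_trace")
  m2 <- mesh_stats(loft_trace(tr, 0.8))
  expect_equal(m2$euler, 2)
  expect_true(m2$watertight)
  # missing slice in range
  tr_bad <- tr
  tr_bad$contours[[2]]$slice <- 3L
  expect_error(loft_trace(tr_bad, 0.8), "contiguous")
})

test_that("lofting is invariant to cyclic contour vertex order", {
  ct1 <- manual_circle(c(1, 2), 1.5, 1)
  ct2 <- manual_circle(c(1.2, 1.9), 1.4, 2)
  rotv <- function(ct, k) {
    n <- nrow(ct$vertices)
    ct$vertices <- ct$vertices[c((k + 1):n, 1:k), ]
    ct
  }
  tr_a <- structure(list(axon_id = "a", contours = list(ct1, ct2),
                         status = "complete", start_slice = 1L),
                    class = "axon_trace")
  tr_b <- tr_a
  tr_b$contours <- list(rotv(ct1, 17), rotv(ct2, 40))
  va <- mesh_stats(loft_trace(tr_a, 0.8))$volume
  vb <- mesh_stats(loft_trace(tr_b, 0.8))$volume
  expect_lt(abs(va - vb), 1e-9 * va)
})

test_that("a lofted phantom axon follows the true trajectory", {
  cf <- phantom_config(n_axons = 1, n_slices = 10, image_size = c(72, 72),
                       diameter_range = c(4, 4), trajectory_amplitude = 1.2,
                       trajectory_wavelength = 10, gap_probability = 0,
                       noise_sd = 0, area_fluctuation_cv = 0, seed = 6)
  ph <- generate_phantom(cf)
  s <- truth_seeds(ph)
  res <- propagate_trace(ph$stack, "axon001", c(s$row_px[1], s$col_px[1]))
  expect_equal(res$trace$status, "complete")
  mesh <- loft_trace(res$trace, cf$z_step)
  truth <- ph$truth$axon_slices
  # ring centroids (excluding cap apices) vs ground-truth centres
  n_ring <- 64
  for (sl in 1:10) {
    ring <- mesh$vertices[(sl - 1) * n_ring + seq_len(n_ring), ]
    cen <- colMeans(ring[, 1:2])
    want <- c(truth$row_um[truth$slice == sl], truth$col_um[truth$slice == sl])
    expect_lt(sqrt(sum((cen - want)^2)), cf$xy_scale)  # within 1 px
  }
})

test_that("mesh statistics are exact on the icosahedron", {
  ico <- make_icosphere(0)
  st <- mesh_stats(ico)
  expect_equal(st$vertex_count, 12)
  expect_equal(st$edge_count, 30)
  expect_equal(st$face_count, 20)
  expect_equal(st$euler, 2)
  expect_true(st$watertight)
  expect_equal(st$components, 1)
})

test_that("HC smoothing preserves volume where plain Laplacian shrinks", {
  ico <- make_icosphere(3)
  v0 <- mesh_stats(ico)$volume
  expect_identical(hc_laplacian_smooth(ico, 0), ico)
  hc <- hc_laplacian_smooth(ico, 10)
  lp <- laplacian_smooth(ico, 10)
  expect_lt(abs(mesh_stats(hc)$volume / v0 - 1), 0.02)
  expect_gt(1 - mesh_stats(lp)$volume / v0, 0.15)
  # connectivity untouched; symmetric solid centroid pinned
  expect_identical(hc$faces, ico$faces)
  expect_lt(max(abs(colMeans(hc$vertices) - colMeans(ico$vertices))), 1e-6)
  # noisy cylinder: radial noise halved on the barrel away from the caps,
  # mean radius kept
  set.seed(12)
  noisy <- make_cylinder(2, 8, n_ring = 48, n_slabs = 14, jitter_sd = 0.05)
  z <- noisy$vertices[, 3]
  body <- which(sqrt(noisy$vertices[, 1]^2 + noisy$vertices[, 2]^2) > 1e-9 &
                  z > min(z) + 1e-9 & z < max(z) - 1e-9)
  r_of <- function(m) sqrt(m$vertices[body, 1]^2 + m$vertices[body, 2]^2)
  sm <- hc_laplacian_smooth(noisy, 10)
  expect_lt(sd(r_of(sm) - 2), 0.5 * sd(r_of(noisy) - 2))
  expect_lt(abs(mean(r_of(sm)) / 2 - 1), 0.02)
  # isolated vertex is an error
  bad <- trimesh(rbind(ico$vertices, c(9, 9, 9)), ico$faces)
  expect_error(hc_laplacian_smooth(bad, 1), "isolated")
})

test_that("quadric decimation hits the target while preserving topology", {
  cyl <- make_cylinder(2, 8, n_ring = 48, n_slabs = 10)
  v0 <- mesh_stats(cyl)$volume
  dec <- quadric_decimate(cyl, 0.38)
  st <- mesh_stats(dec)
  expect_lte(st$vertex_count, ceiling(0.38 * mesh_stats(cyl)$vertex_count))
  expect_lt(abs(st$volume / v0 - 1), 0.03)
  expect_equal(st$euler, 2)
  expect_true(st$watertight)
  expect_equal(st$components, 1)
  expect_equal(attr(dec, "achieved_fraction"),
               st$vertex_count / mesh_stats(cyl)$vertex_count,
               tolerance = 1e-9)
  # near-unity fraction collapses at most a handful of vertices
  dec2 <- quadric_decimate(cyl, 0.999)
  expect_gte(mesh_stats(dec2)$vertex_count,
             mesh_stats(cyl)$vertex_count - 2)
  # genus-1 torus keeps Euler characteristic 0
  tor <- make_torus()
  expect_equal(mesh_stats(tor)$euler, 0)
  dtor <- quadric_decimate(tor, 0.5)
  expect_equal(mesh_stats(dtor)$euler, 0)
  expect_true(mesh_stats(dtor)$watertight)
})

test_that("overlap errors equal the brute-force containment count", {
  c1 <- make_cylinder(2, 8, n_ring = 24, n_slabs = 6)
  c2 <- make_cylinder(2, 8, n_ring = 24, n_slabs = 6)
  # ~50% radial overlap; the uneven offsets keep every vertex strictly off
  # the other solid's surface (points on a surface are not strictly inside)
  c2$vertices[, 1] <- c2$vertices[, 1] + 2.13
  c2$vertices[, 2] <- c2$vertices[, 2] + 0.41
  c2$vertices[, 3] <- c2$vertices[, 3] + 0.37
  ov <- overlap_errors(list(a = c1, b = c2))
  want_ab <- sum(oracle_points_inside(c1$vertices, c2))
  want_ba <- sum(oracle_points_inside(c2$vertices, c1))
  got <- ov$pairs
  expect_equal(got$n_inside[got$mesh_a == "a"], want_ab)
  expect_equal(got$n_inside[got$mesh_a == "b"], want_ba)
  expect_equal(ov$total, want_ab + want_ba)
  expect_gt(ov$total, 0)
  # disjoint cylinders: zero
  c3 <- make_cylinder(2, 8, n_ring = 24, n_slabs = 6)
  c3$vertices[, 1] <- c3$vertices[, 1] + 10
  expect_equal(overlap_errors(list(a = c1, b = c3))$total, 0)
  # non-watertight input is rejected by name
  open <- trimesh(c1$vertices, c1$faces[-1, ])
  expect_error(overlap_errors(list(good = c2, broken = open)), "broken")
})

test_that("smoothing reduces spike-driven overlaps between adjacent axons", {
  # two copies of a raw (unsmoothed, staircase-contour) segmented axon mesh
  # placed so that only their surface spikes interpenetrate; HC smoothing
  # flattens the spikes and must not increase the overlap count
  cf <- phantom_config(n_axons = 1, n_slices = 10, image_size = c(64, 64),
                       diameter_range = c(4, 4), trajectory_amplitude = 0.2,
                       gap_probability = 0, noise_sd = 0,
                       area_fluctuation_cv = 0.05, seed = 6)
  ph <- generate_phantom(cf)
  s <- truth_seeds(ph)
  res <- propagate_trace(ph$stack, "axon001", c(s$row_px[1], s$col_px[1]),
                         config = segmentation_config(smooth_window = 1))
  m1 <- loft_trace(res$trace, cf$z_step)
  cen <- colMeans(m1$vertices[1:64, 1:2])
  rr <- sqrt((m1$vertices[, 1] - cen[1])^2 + (m1$vertices[, 2] - cen[2])^2)
  r_mean <- mean(rr[rr > 0.5])
  m2 <- m1
  m2$vertices[, 1] <- m2$vertices[, 1] + 2 * r_mean + 0.1
  m2$vertices[, 3] <- m2$vertices[, 3] + 0.13
  ov0 <- overlap_errors(list(a = m1, b = m2))$total
  expect_gt(ov0, 0)
  sm <- lapply(list(a = m1, b = m2), hc_laplacian_smooth, iterations = 10)
  ov1 <- overlap_errors(sm)$total
  expect_lte(ov1, ov0)
})

test_that("PLY and VRML exports round-trip losslessly", {
  td <- withr::local_tempdir()
  ico <- make_icosphere(1)
  p1 <- file.path(td, "ico.ply")
  export_mesh(ico, p1)
  back <- import_mesh(p1)
  expect_identical(back$faces, ico$faces)
  expect_lt(max(abs(back$vertices - ico$vertices)), 1e-6)
  # multi-axon VRML scene: one named node per trace
  cyl <- make_cylinder(1, 4, n_ring = 32, n_slabs = 4)
  p2 <- file.path(td, "scene.wrl")
  export_mesh(list(axon001 = ico, axon002 = cyl, axon003 = ico), p2)
  scene <- import_mesh(p2)
  expect_named(scene, c("axon001", "axon002", "axon003"))
  expect_equal(nrow(scene$axon002$vertices), nrow(cyl$vertices))
  expect_identical(scene$axon002$faces, cyl$faces)
  expect_lt(max(abs(scene$axon001$vertices - ico$vertices)), 1e-6)
  expect_error(export_mesh(ico, file.path(td, "m.obj")), "extension")
})
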