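# Independent oracles and fixture builders used across the test files.

# Brute-force seeded fill: synchronous frontier dilation with the same
# acceptance predicate (|I - I(seed)| <= tol, 4-connected). Implemented
# differently from the package's BFS so it can serve as an oracle.
oracle_flood_fill <- function(img, seed, tol) {
  ok <- abs(img - img[seed[1], seed[2]]) <= tol
  reg <- matrix(FALSE, nrow(img), ncol(img))
  reg[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- reg
    grown[-1, ] <- grown[-1, ] | reg[-nrow(reg), ]
    grown[-nrow(reg), ] <- grown[-nrow(reg), ] | reg[-1, ]
    grown[, -1] <- grown[, -1] | reg[, -ncol(reg)]
    grown[, -ncol(reg)] <- grown[, -ncol(reg)] | reg[, -1]
    grown <- grown & ok
    if (identical(grown, reg)) break
    reg <- grown
  }
  reg
}

# Random smooth "blob" test image in 0..255 (sum of Gaussian bumps + noise).
random_blob_image <- function(nr, nc, n_blobs = 5, noise = 10) {
  img <- matrix(0, nr, nc)
  gr <- row(img); gc <- col(img)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
    s <- runif(1, 2, nr / 4); a <- runif(1, 60, 220)
    img <- img + a * exp(-((gr - cy)^2 + (gc - cx)^2) / (2 * s^2))
  }
  img <- img + rnorm(nr * nc, 0, noise)
  matrix(pmin(pmax(round(img), 0), 255), nr, nc)
}

# Binary myelin-ring slice drawn directly (no phantom machinery):
# bright lumen and background, dark ring, optional angular gap.
ring_image <- function(n = 41, r_in = 8, r_out = 12, gap_deg = NULL,
                       lumen = 255, myelin = 30, background = 245) {
  img <- matrix(background, n, n)
  cen <- (n + 1) / 2
  d <- sqrt((row(img) - cen)^2 + (col(img) - cen)^2)
  ring <- d > r_in & d <= r_out
  if (!is.null(gap_deg)) {
    ang <- (atan2(col(img) - cen, row(img) - cen) * 180 / pi) %% 360
    ring[ang >= gap_deg[1] & ang < gap_deg[2]] <- FALSE
  }
  img[ring] <- myelin
  img[d <= r_in] <- lumen
  img
}

# Pure-R point-in-mesh oracle (z-axis ray parity, 2D projected triangle
# containment + plane crossing), independent of the C++ ray caster.
oracle_points_inside <- function(pts, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    hits <- 0L
    for (k in seq_len(nrow(f))) {
      a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
      # barycentric test in the xy plane
      d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
      if (abs(d) < 1e-14) next
      w1 <- ((b[2] - cc[2]) * (p[1] - cc[1]) + (cc[1] - b[1]) * (p[2] - cc[2])) / d
      w2 <- ((cc[2] - a[2]) * (p[1] - cc[1]) + (a[1] - cc[1]) * (p[2] - cc[2])) / d
      w3 <- 1 - w1 - w2
      if (w1 < 0 || w2 < 0 || w3 < 0) next
      z <- w1 * a[3] + w2 * b[3] + w3 * cc[3]
      if (z > p[3] + 1e-12) hits <- hits + 1L
    }
    hits %% 2L == 1L
  }, logical(1))
}

# Parametric torus mesh (genus 1), for topology-preservation checks.
make_torus <- function(R = 3, r = 1, nu = 24, nv = 16) {
  u <- 2 * pi * (seq_len(nu) - 1) / nu
  v <- 2 * pi * (seq_len(nv) - 1) / nv
  verts <- matrix(0, nu * nv, 3)
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    verts[(i - 1) * nv + j, ] <- c((R + r * cos(v[j])) * cos(u[i]),
                                   (R + r * cos(v[j])) * sin(u[i]),
                                   r * sin(v[j]))
  }
  faces <- NULL
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    i2 <- i %% nu + 1; j2 <- j %% nv + 1
    a <- (i - 1) * nv + j; b <- (i2 - 1) * nv + j
    cc <- (i2 - 1) * nv + j2; d <- (i - 1) * nv + j2
    faces <- rbind(faces, c(a, b, cc), c(a, cc, d))
  }
  trimesh(verts, faces)
}

# Seeds at the true slice-1 centres of a phantom, and the operator-emulating
# replacement-seed hook used to continue tracing after an abortion.
truth_seeds <- function(ph) {
  tr <- ph$truth$axon_slices
  s1 <- tr[tr$slice == 1, ]
  xy <- ph$config$xy_scale
  data.frame(axon_id = s1$axon_id,
             row_px = round(s1$row_um / xy + 0.5),
             col_px = round(s1$col_um / xy + 0.5))
}

truth_hook <- function(ph, kept_slices = NULL) {
  tr <- ph$truth$axon_slices
  xy <- ph$config$xy_scale
  if (is.null(kept_slices)) kept_slices <- seq_len(ph$config$n_slices)
  function(event) {
    os <- kept_slices[event$slice]
    row <- tr[tr$axon_id == event$axon_id & tr$slice == os, ]
    if (!nrow(row)) return(NULL)
    c(round(row$row_um[1] / xy + 0.5), round(row$col_um[1] / xy + 0.5))
  }
}
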