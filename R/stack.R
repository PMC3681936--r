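#' Physical calibration of an image stack
#'
#' Binds the pixel raster to physical units: the in-plane scale in
#' micrometres per pixel, the section (z) spacing in micrometres per slice,
#' and an optional isotropic shrinkage-compensation factor applied when
#' converting pixel measurements to physical units.
#'
#' @param xy_scale In-plane scale, µm per pixel. Must be > 0.
#' @param z_step Section spacing, µm per slice. Must be > 0.
#' @param shrinkage_factor Dimensionless multiplier compensating tissue
#'   shrinkage during fixation/embedding; lengths in µm are multiplied by
#'   this factor. Default 1 (no compensation).
#' @return An object of class `"calibration"`.
#' @examples
#' cal <- calibration(xy_scale = 1 / 2.6, z_step = 0.8)
#' stack_depth(cal, n_slices = 625) # 500 µm
#' @export
calibration <- function(xy_scale, z_step, shrinkage_factor = 1) {
  stopifnot(is.numeric(xy_scale), length(xy_scale) == 1, xy_scale > 0,
            is.numeric(z_step), length(z_step) == 1, z_step > 0,
            is.numeric(shrinkage_factor), shrinkage_factor > 0)
  structure(list(xy_scale = xy_scale, z_step = z_step,
                 shrinkage_factor = shrinkage_factor),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.4g um/px (%.3g px/um), z step %.4g um, shrinkage x%.3g\n",
              x$xy_scale, 1 / x$xy_scale, x$z_step, x$shrinkage_factor))
  invisible(x)
}

#' Convert between pixel and micrometre units
#'
#' @param x Numeric values to convert.
#' @param cal A [calibration()] object.
#' @return Converted numeric values; `px_to_um()` applies the shrinkage
#'   compensation factor, `um_to_px()` removes it.
#' @export
px_to_um <- function(x, cal) x * cal$xy_scale * cal$shrinkage_factor

#' @rdname px_to_um
#' @export
um_to_px <- function(x, cal) x / (cal$xy_scale * cal$shrinkage_factor)

#' Physical depth spanned by a stack
#'
#' @param cal A [calibration()] object.
#' @param n_slices Number of slices.
#' @return Depth in µm (`n_slices * z_step`).
#' @export
stack_depth <- function(cal, n_slices) {
  stopifnot(n_slices >= 1)
  n_slices * cal$z_step
}

#' Construct an image stack
#'
#' A z-ordered stack of equally sized 8-bit grayscale slices with physical
#' calibration. Pixel coordinates are 1-based `(row, col)` as usual in R;
#' physical coordinates refer to pixel centres in µm.
#'
#' @param slices List of numeric matrices (intensities in 0..255), ordered by
#'   increasing z.
#' @param calibration A [calibration()] object.
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(slices, calibration) {
  stopifnot(is.list(slices), length(slices) >= 1,
            inherits(calibration, "calibration"))
  dims <- vapply(slices, dim, integer(2))
  if (ncol(dims) > 1 && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop("all slices must have the same dimensions")
  structure(list(slices = slices, calibration = calibration),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("image_stack: %d slices of %d x %d px\n",
              length(x$slices), d[1], d[2]))
  print(x$calibration)
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$slices)

#' Convert a color stack (or slice) to 8-bit grayscale
#'
#' Uses the standard Rec. 601 luminance weighting
#' `0.299 R + 0.587 G + 0.114 B`. Grayscale input is returned unchanged
#' (idempotent).
#'
#' @param x An `image_stack`, a 2D matrix, or an H x W x 3 array with
#'   channels in 0..255 (or 0..1, which is rescaled).
#' @return Same container type with 8-bit grayscale slices.
#' @export
to_grayscale <- function(x) {
  if (inherits(x, "image_stack")) {
    x$slices <- lapply(x$slices, to_grayscale)
    return(x)
  }
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    if (dim(x)[3] == 1) return(x[, , 1])
    if (dim(x)[3] < 3) stop("expected 3-channel input")
    g <- matrix(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3],
                dim(x)[1], dim(x)[2])
    if (max(x) <= 1) g <- g * 255
    return(g)
  }
  stop("cannot interpret input as image")
}

#' Derive in-plane calibration from a reference length
#'
#' Computes the µm-per-pixel scale from a structure of known physical size
#' measured in pixels, e.g. a microscopically measured nerve diameter.
#'
#' @param stack Optional `image_stack`; its z step and shrinkage factor are
#'   carried over. If `NULL`, `z_step` must be given.
#' @param reference_length_um Known physical length, µm (> 0).
#' @param measured_length_px The same length measured on the image, px (> 0).
#' @param z_step Section spacing, µm (used when `stack` is `NULL`).
#' @return A [calibration()] with `xy_scale = reference_length_um /
#'   measured_length_px`.
#' @examples
#' calibrate_from_reference(NULL, 151.6, 151.6 * 2.6, z_step = 0.8)
#' @export
calibrate_from_reference <- function(stack, reference_length_um,
                                     measured_length_px, z_step = NULL) {
  if (!is.numeric(reference_length_um) || reference_length_um <= 0 ||
      !is.numeric(measured_length_px) || measured_length_px <= 0)
    stop("reference and measured lengths must be positive")
  if (!is.null(stack)) {
    stopifnot(inherits(stack, "image_stack"))
    z <- stack$calibration$z_step
    s <- stack$calibration$shrinkage_factor
  } else {
    if (is.null(z_step)) stop("z_step required when no stack is given")
    z <- z_step
    s <- 1
  }
  calibration(xy_scale = reference_length_um / measured_length_px,
              z_step = z, shrinkage_factor = s)
}

#' Crop all slices of a stack to a rectangle
#'
#' @param stack An `image_stack`.
#' @param rect Integer vector `c(row0, col0, height, width)` (1-based,
#'   inclusive origin). Must lie inside the image.
#' @return Cropped `image_stack`; calibration unchanged.
#' @export
crop_stack <- function(stack, rect) {
  stopifnot(inherits(stack, "image_stack"), length(rect) == 4)
  d <- dim(stack$slices[[1]])
  r0 <- rect[1]; c0 <- rect[2]; h <- rect[3]; w <- rect[4]
  if (r0 < 1 || c0 < 1 || h < 1 || w < 1 ||
      r0 + h - 1 > d[1] || c0 + w - 1 > d[2])
    stop("crop rectangle out of bounds")
  stack$slices <- lapply(stack$slices,
                         function(s) s[r0:(r0 + h - 1), c0:(c0 + w - 1), drop = FALSE])
  stack
}

#' Rotate all slices by multiples of 90 degrees clockwise
#'
#' @param stack An `image_stack`.
#' @param k Number of clockwise quarter turns (default 1).
#' @return Rotated `image_stack`; calibration unchanged.
#' @export
rotate90_stack <- function(stack, k = 1) {
  stopifnot(inherits(stack, "image_stack"))
  k <- ((k %% 4) + 4) %% 4
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (i in seq_len(k)) stack$slices <- lapply(stack$slices, rot1)
  stack
}

# Bilinear sampling of `img` at fractional (row, col) coordinates.
# Out-of-range samples take `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # edge pixels: clamp to allow sampling exactly on the last row/col
  edge <- !ok & r >= 1 & r <= nr & c >= 1 & c <= nc
  out <- rep(fill, length(r))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    v00 <- img[i00]
    v10 <- img[cbind(r0[ok] + 1, c0[ok])]
    v01 <- img[cbind(r0[ok], c0[ok] + 1)]
    v11 <- img[cbind(r0[ok] + 1, c0[ok] + 1)]
    out[ok] <- v00 * (1 - fr[ok]) * (1 - fc[ok]) + v10 * fr[ok] * (1 - fc[ok]) +
      v01 * (1 - fr[ok]) * fc[ok] + v11 * fr[ok] * fc[ok]
  }
  if (any(edge))
    out[edge] <- img[cbind(pmin(pmax(round(r[edge]), 1), nr),
                           pmin(pmax(round(c[edge]), 1), nc))]
  out
}

#' Apply (or undo) a rigid in-plane transform to a slice
#'
#' The forward transform maps a source point `p` (px, `(row, col)`) to
#' `R(theta) (p - center) + center + (dr, dc)`, i.e. rotation about the image
#' centre followed by translation. Rendering uses inverse mapping with
#' bilinear interpolation.
#'
#' @param img Numeric matrix.
#' @param dr,dc Translation in pixels (rows, cols).
#' @param theta_deg Rotation in degrees (counter-clockwise in `(row, col)`
#'   axes).
#' @param inverse If `TRUE`, applies the inverse transform (used to undo an
#'   estimated misalignment).
#' @param fill Intensity for samples falling outside the source image.
#' @return Transformed matrix of the same size.
#' @export
apply_rigid <- function(img, dr, dc, theta_deg, inverse = FALSE, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  cen <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- theta_deg * pi / 180
  gr <- matrix(seq_len(nr), nr, nc)
  gc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (!inverse) {
    # output(q) = input(T^{-1} q)
    yr <- gr - cen[1] - dr
    yc <- gc - cen[2] - dc
    sr <- cos(th) * yr + sin(th) * yc + cen[1]
    sc <- -sin(th) * yr + cos(th) * yc + cen[2]
  } else {
    # output(q) = input(T q)
    yr <- gr - cen[1]
    yc <- gc - cen[2]
    sr <- cos(th) * yr - sin(th) * yc + cen[1] + dr
    sc <- sin(th) * yr + cos(th) * yc + cen[2] + dc
  }
  matrix(bilinear_sample(img, as.vector(sr), as.vector(sc), fill = fill),
         nr, nc)
}

# separable Gaussian blur; reduces interpolation bias during registration
gaussian_blur <- function(img, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
  conv1 <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# Phase correlation between two equally sized matrices.
# Returns list(shift = c(dr, dc), peak): b approx equal to a shifted by
# (dr, dc), i.e. b(p) = a(p - shift). Subpixel refinement by parabolic fit.
phase_correlate <- function(a, b, window = TRUE) {
  nr <- nrow(a); nc <- ncol(a)
  if (window) {
    wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
    wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
    w <- outer(wr, wc)
    a <- (a - mean(a)) * w
    b <- (b - mean(b)) * w
  }
  fa <- fft(a); fb <- fft(b)
  cp <- fb * Conj(fa)
  cp <- cp / (Mod(cp) + 1e-12)
  corr <- Re(fft(cp, inverse = TRUE)) / (nr * nc)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dr <- wrap(pk[1], nr); dc <- wrap(pk[2], nc)
  # parabolic subpixel refinement along each axis
  sub <- function(im1, i0, ip1) {
    den <- im1 - 2 * i0 + ip1
    if (abs(den) < 1e-12) return(0)
    d <- 0.5 * (im1 - ip1) / den
    max(min(d, 0.5), -0.5)
  }
  idx <- function(i, n) ((i - 1) %% n) + 1
  r0 <- pk[1]; c0 <- pk[2]
  ddr <- sub(corr[idx(r0 - 1, nr), c0], corr[r0, c0], corr[idx(r0 + 1, nr), c0])
  ddc <- sub(corr[r0, idx(c0 - 1, nc)], corr[r0, c0], corr[r0, idx(c0 + 1, nc)])
  list(shift = c(dr + ddr, dc + ddc), peak = corr[r0, c0])
}

#' Rigidly align the slices of a stack
#'
#' Registers each slice to its (already aligned) predecessor by translation
#' and rotation only — no shear or scale — anchoring the chain at the first
#' slice. Rotation is estimated by a coarse-to-fine search maximizing the
#' phase-correlation peak; translation by subpixel phase correlation.
#'
#' @param stack An `image_stack` with at least 2 slices.
#' @param angle_range Half-width of the rotation search, degrees.
#' @param angle_step Coarse search step, degrees.
#' @param fill Fill intensity for resampled out-of-frame pixels.
#' @return `list(stack, transforms)`: the aligned stack and a data frame
#'   `(slice, dr_px, dc_px, theta_deg)` of the estimated per-slice forward
#'   misalignments (identity for slice 1).
#' @export
align_rigid <- function(stack, angle_range = 5, angle_step = 1, fill = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$slices)
  if (n < 2) stop("need at least 2 slices to align")
  for (i in seq_len(n))
    if (sd(stack$slices[[i]]) == 0)
      stop(sprintf("degenerate (blank) slice %d: cannot align", i))
  if (is.null(fill)) fill <- median(stack$slices[[1]])
  aligned <- stack$slices
  tf <- data.frame(slice = seq_len(n), dr_px = 0, dc_px = 0, theta_deg = 0)
  for (i in 2:n) {
    fixed <- gaussian_blur(aligned[[i - 1]])
    moving <- gaussian_blur(stack$slices[[i]])
    score <- function(th) {
      und <- if (th == 0) moving else
        apply_rigid(moving, 0, 0, th, inverse = TRUE, fill = fill)
      phase_correlate(fixed, und)$peak
    }
    if (angle_range > 0) {
      grid <- seq(-angle_range, angle_range, by = angle_step)
      sc <- vapply(grid, score, numeric(1))
      th0 <- grid[which.max(sc)]
      opt <- optimize(score, interval = c(th0 - angle_step, th0 + angle_step),
                      maximum = TRUE, tol = 0.01)
      theta <- opt$maximum
    } else theta <- 0
    und <- if (theta == 0) moving else
      apply_rigid(moving, 0, 0, theta, inverse = TRUE, fill = fill)
    pc <- phase_correlate(fixed, und)
    # und(p) = fixed(p - s) => residual translation s in the de-rotated frame;
    # forward-transform translation t = R(theta) s
    s <- pc$shift
    thr <- theta * pi / 180
    t_fwd <- c(cos(thr) * s[1] + -sin(thr) * s[2],
               sin(thr) * s[1] + cos(thr) * s[2])
    # local SSD refinement over (dr, dc, theta) on the interior region
    nr <- nrow(fixed); ncc <- ncol(fixed)
    mr <- max(3, ceiling(0.1 * nr)); mc <- max(3, ceiling(0.1 * ncc))
    ir <- (mr + 1):(nr - mr); ic <- (mc + 1):(ncc - mc)
    fx <- fixed[ir, ic]
    ssd <- function(p) {
      u <- apply_rigid(moving, p[1], p[2], p[3], inverse = TRUE, fill = fill)
      mean((u[ir, ic] - fx)^2)
    }
    opt2 <- stats::optim(c(t_fwd[1], t_fwd[2], theta), ssd,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 300))
    t_fwd <- opt2$par[1:2]; theta <- opt2$par[3]
    aligned[[i]] <- apply_rigid(stack$slices[[i]], t_fwd[1], t_fwd[2], theta,
                                inverse = TRUE, fill = fill)
    tf$dr_px[i] <- t_fwd[1]; tf$dc_px[i] <- t_fwd[2]; tf$theta_deg[i] <- theta
  }
  out <- stack
  out$slices <- aligned
  list(stack = out, transforms = tf)
}

#' Read an image stack from files
#'
#' Accepts a directory of numbered PNG/TIFF slices, a character vector of
#' file paths, or a single multi-page TIFF. Color images are converted to
#' 8-bit grayscale.
#'
#' @param path Directory, file vector, or multi-page TIFF path.
#' @param calibration A [calibration()] object to attach.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, calibration) {
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(files)]
    if (!length(files)) stop("no PNG/TIFF files in directory")
    return(read_stack(files, calibration))
  }
  read1 <- function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- switch(ext,
                  png = png::readPNG(f),
                  tif = ,
                  tiff = tiff::readTIFF(f, all = FALSE),
                  stop("unsupported image format: ", ext))
    to_grayscale(img * if (max(img) <= 1) 255 else 1)
  }
  if (length(path) == 1) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      slices <- lapply(pages, function(p)
        to_grayscale(p * if (max(p) <= 1) 255 else 1))
      return(image_stack(slices, calibration))
    }
  }
  image_stack(lapply(path, read1), calibration)
}

#' Write an image stack to numbered PNG files or a multi-page TIFF
#'
#' @param stack An `image_stack`.
#' @param path Output directory (PNG series) or a `.tif` path (multi-page).
#' @param format `"png"` or `"tiff"`.
#' @param prefix File-name prefix for the PNG series.
#' @return Invisibly, the written file paths.
#' @export
write_stack <- function(stack, path, format = c("png", "tiff"),
                        prefix = "slice") {
  format <- match.arg(format)
  norm <- lapply(stack$slices, function(s) pmin(pmax(s / 255, 0), 1))
  if (format == "png") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, sprintf("%s_%04d.png", prefix,
                                     seq_along(norm) - 1))
    for (i in seq_along(norm)) png::writePNG(norm[[i]], files[i])
    return(invisible(files))
  }
  tiff::writeTIFF(norm, path)
  invisible(path)
}
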