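#' Configuration for the synthetic nerve phantom
#'
#' Describes a synthetic cross-section image stack of a peripheral nerve:
#' bright axon lumina surrounded by dark myelin rings on a bright background,
#' with sinuous per-slice trajectories, per-slice lumen-area fluctuation,
#' occasional myelin-ring gaps ("open boundaries"), additive intensity noise
#' and optional rigid per-slice misalignment. The defaults emulate a
#' toluidine-blue-stained nerve imaged at 2.6 px/µm and sectioned at 0.8 µm:
#' 120 axons with inner diameters between 1.14 and 6.04 µm over 32 slices.
#'
#' @param n_axons Number of axons.
#' @param n_slices Number of sections (z planes).
#' @param image_size Image height and width in pixels `c(H, W)`.
#' @param xy_scale In-plane scale, µm per pixel.
#' @param z_step Section spacing, µm.
#' @param diameter_range Inner-lumen diameter range `c(min, max)` in µm;
#'   diameters are drawn from a lognormal clipped to this range. `min` must
#'   span at least 2 pixels.
#' @param myelin_thickness Myelin ring thickness, µm.
#' @param trajectory_amplitude Per-axis amplitude of the sinuous axon
#'   trajectory, µm.
#' @param trajectory_wavelength Nominal trajectory wavelength along z, µm.
#' @param area_fluctuation_cv Coefficient of variation of the multiplicative
#'   (lognormal) per-slice lumen-area jitter.
#' @param gap_probability Probability per axon per slice of a myelin-ring gap
#'   (open boundary). May also be a function of the axon's normalized radial
#'   distance from the nerve centre (in `[0, 1]`) returning a probability,
#'   for radially varying artifact rates.
#' @param gap_arc Angular width of a gap, degrees.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (8-bit units).
#' @param misalignment_sd Per-slice rigid jitter `c(sd_px, sd_deg)`
#'   (translation SD in pixels, rotation SD in degrees); slice 1 is never
#'   jittered so that recovered alignments are comparable to ground truth.
#' @param background_level,lumen_level,myelin_level 8-bit intensities of the
#'   three tissue classes. Lumen and background must both be brighter than
#'   the myelin ring, and are deliberately close to each other: an open
#'   boundary then lets region growing leak from lumen to background.
#' @param antialias If `TRUE` (default), pixel intensities at class borders
#'   are area-weighted by 3 x 3 subpixel coverage, emulating optical blur;
#'   the label image always uses the pixel-centre test and stays binary.
#' @param seed RNG seed making the phantom reproducible.
#' @return An object of class `"phantom_config"`.
#' @export
phantom_config <- function(n_axons = 120,
                           n_slices = 32,
                           image_size = c(320, 320),
                           xy_scale = 1 / 2.6,
                           z_step = 0.8,
                           diameter_range = c(1.14, 6.04),
                           myelin_thickness = 0.6,
                           trajectory_amplitude = 1.0,
                           trajectory_wavelength = 30,
                           area_fluctuation_cv = 0.1,
                           gap_probability = 0.05,
                           gap_arc = 60,
                           noise_sd = 4,
                           misalignment_sd = c(0, 0),
                           background_level = 245,
                           lumen_level = 255,
                           myelin_level = 30,
                           antialias = TRUE,
                           seed = 1L) {
  stopifnot(n_axons >= 1, n_slices >= 1, length(image_size) == 2,
            all(image_size >= 16), xy_scale > 0, z_step > 0,
            length(diameter_range) == 2,
            diameter_range[1] > 0, diameter_range[2] >= diameter_range[1],
            myelin_thickness > 0, trajectory_amplitude >= 0,
            trajectory_wavelength > 0, area_fluctuation_cv >= 0,
            gap_arc > 0, gap_arc <= 360, noise_sd >= 0,
            length(misalignment_sd) == 2, all(misalignment_sd >= 0))
  if (diameter_range[1] < 2 * xy_scale)
    stop("minimum lumen diameter must span at least 2 pixels")
  if (lumen_level <= myelin_level || background_level <= myelin_level)
    stop("lumen and background must be brighter than the myelin ring")
  if (!is.function(gap_probability))
    stopifnot(gap_probability >= 0, gap_probability <= 1)
  structure(list(n_axons = as.integer(n_axons),
                 n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size), xy_scale = xy_scale,
                 z_step = z_step, diameter_range = diameter_range,
                 myelin_thickness = myelin_thickness,
                 trajectory_amplitude = trajectory_amplitude,
                 trajectory_wavelength = trajectory_wavelength,
                 area_fluctuation_cv = area_fluctuation_cv,
                 gap_probability = gap_probability, gap_arc = gap_arc,
                 noise_sd = noise_sd, misalignment_sd = misalignment_sd,
                 background_level = background_level,
                 lumen_level = lumen_level, myelin_level = myelin_level,
                 antialias = isTRUE(antialias), seed = seed),
            class = "phantom_config")
}

# Deterministic golden-angle spiral packing of discs with per-axon exclusion
# radii inside a nerve of radius R (µm, origin at nerve centre).
place_axons <- function(excl_radius, R, step_um = 0.4) {
  n <- length(excl_radius)
  # placement in axon order (sizes are i.i.d. across it), so that axon size
  # stays independent of the distance to the nerve centre
  ord <- seq_len(n)
  ctr <- matrix(NA_real_, n, 2)
  golden <- pi * (3 - sqrt(5))
  kmax <- 200000L
  k_all <- seq_len(kmax) - 1L
  rho_all <- step_um * sqrt(k_all)
  ang_all <- k_all * golden
  cand_r <- rho_all * cos(ang_all)
  cand_c <- rho_all * sin(ang_all)
  for (i in ord) {
    ri <- excl_radius[i]
    ok <- rho_all <= (R - ri)
    placed <- !is.na(ctr[, 1])
    idx <- which(ok)
    found <- FALSE
    for (k in idx) {
      if (any(placed)) {
        dd <- sqrt((ctr[placed, 1] - cand_r[k])^2 +
                   (ctr[placed, 2] - cand_c[k])^2)
        if (any(dd < excl_radius[placed] + ri)) next
      }
      ctr[i, ] <- c(cand_r[k], cand_c[k])
      found <- TRUE
      break
    }
    if (!found) stop("cannot place axons: packing failed, enlarge image_size ",
                     "or reduce n_axons")
  }
  ctr
}

#' Generate a synthetic nerve image stack with ground truth
#'
#' Renders the phantom described by a [phantom_config()]: for every axon and
#' slice a bright circular lumen surrounded by a dark myelin annulus is drawn
#' analytically (pixel-centre inclusion test) at the axon's trajectory
#' position, optionally with a background-intensity arc cut into the ring
#' (an open boundary), per-slice rigid misalignment, and additive noise.
#' Axons are packed deterministically on a golden-angle spiral, in axon
#' order, with exclusion radii that keep rings from colliding on any slice.
#'
#' @param config A [phantom_config()].
#' @return An object of class `"nerve_phantom"`: a list with
#'   \describe{
#'     \item{stack}{the rendered [image_stack()] (8-bit grayscale);}
#'     \item{labels}{list of integer matrices labelling each lumen pixel with
#'       its axon index (0 = not lumen), noiseless and exact;}
#'     \item{truth}{ground truth: `axons` (per-axon nominal geometry),
#'       `axon_slices` (per axon per slice centre, analytic and pixel-counted
#'       lumen area, gap log), `transforms` (applied per-slice rigid
#'       misalignment);}
#'     \item{config}{the configuration echo.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_config(n_axons = 5, n_slices = 4,
#'                                       image_size = c(96, 96)))
#' ph$stack
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  H <- cf$image_size[1]; W <- cf$image_size[2]
  cal <- calibration(cf$xy_scale, cf$z_step)
  n <- cf$n_axons; ns <- cf$n_slices
  # nominal inner diameters: clipped lognormal, most mass near ~1.3-2.3 um
  if (diff(cf$diameter_range) == 0) {
    d <- rep(cf$diameter_range[1], n)
  } else {
    d <- rlnorm(n, meanlog = log(1.9), sdlog = 0.35)
    d <- pmin(pmax(d, cf$diameter_range[1]), cf$diameter_range[2])
  }
  r_lumen <- d / 2
  r_out <- r_lumen + cf$myelin_thickness
  amp <- cf$trajectory_amplitude
  sep_margin <- 0.15
  excl <- r_out + sqrt(2) * amp + sep_margin / 2
  R_nerve <- (min(H, W) / 2 - 3) * cf$xy_scale
  ctr0 <- place_axons(excl, R_nerve)  # µm, origin at nerve centre
  # image-frame physical coords: pixel (r, c) centre at ((r-.5), (c-.5))*scale
  cen_um <- c(H, W) / 2 * cf$xy_scale
  # stochastic per-axon trajectory parameters
  phase <- matrix(runif(2 * n, 0, 2 * pi), n, 2)
  wl <- matrix(cf$trajectory_wavelength * runif(2 * n, 0.7, 1.3), n, 2)
  # per-slice multiplicative area jitter
  cv <- cf$area_fluctuation_cv
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    jit <- matrix(rlnorm(n * ns, meanlog = -sdl^2 / 2, sdlog = sdl), n, ns)
  } else jit <- matrix(1, n, ns)
  # gap (open-boundary) log
  dist0 <- sqrt(rowSums(ctr0^2))
  gp <- if (is.function(cf$gap_probability))
    vapply(dist0 / R_nerve, cf$gap_probability, numeric(1))
  else rep(cf$gap_probability, n)
  gap <- matrix(FALSE, n, ns)
  if (any(gp > 0)) gap[] <- matrix(rbinom(n * ns, 1, rep(gp, ns)), n, ns) == 1
  gap_angle <- matrix(runif(n * ns, 0, 360), n, ns)
  gap_angle[!gap] <- NA_real_   # meaningful only where a gap exists
  # per-slice rigid misalignment (slice 1 fixed)
  tf <- data.frame(slice = seq_len(ns), dr_px = 0, dc_px = 0, theta_deg = 0)
  if (any(cf$misalignment_sd > 0) && ns > 1) {
    tf$dr_px[-1] <- rnorm(ns - 1, 0, cf$misalignment_sd[1])
    tf$dc_px[-1] <- rnorm(ns - 1, 0, cf$misalignment_sd[1])
    tf$theta_deg[-1] <- rnorm(ns - 1, 0, cf$misalignment_sd[2])
  }
  z <- (seq_len(ns) - 1) * cf$z_step
  slices <- vector("list", ns)
  labels <- vector("list", ns)
  rec <- vector("list", ns)
  cen_px <- c((H + 1) / 2, (W + 1) / 2)
  for (s in seq_len(ns)) {
    img <- matrix(cf$background_level, H, W)
    lab <- matrix(0L, H, W)
    th <- tf$theta_deg[s] * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    area_px <- numeric(n)
    cr_um <- cc_um <- numeric(n)
    for (i in seq_len(n)) {
      pos <- ctr0[i, ] + amp * sin(2 * pi * z[s] / wl[i, ] + phase[i, ])
      cr_um[i] <- pos[1] + cen_um[1]
      cc_um[i] <- pos[2] + cen_um[2]
      # slice-frame (possibly misaligned) centre in px
      p_px <- c(cr_um[i], cc_um[i]) / cf$xy_scale + 0.5
      q <- as.vector(rot %*% (p_px - cen_px)) + cen_px +
        c(tf$dr_px[s], tf$dc_px[s])
      rl_px <- r_lumen[i] * sqrt(jit[i, s]) / cf$xy_scale
      ro_px <- rl_px + cf$myelin_thickness / cf$xy_scale
      rr <- max(1L, floor(q[1] - ro_px - 1)):min(H, ceiling(q[1] + ro_px + 1))
      cc <- max(1L, floor(q[2] - ro_px - 1)):min(W, ceiling(q[2] + ro_px + 1))
      if (!length(rr) || !length(cc)) next
      gr <- matrix(rr, length(rr), length(cc))
      gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      a0 <- (gap_angle[i, s] + tf$theta_deg[s]) %% 360
      classify <- function(pr, pc) {
        dd <- sqrt((pr - q[1])^2 + (pc - q[2])^2)
        in_lum <- dd <= rl_px
        in_mye <- dd <= ro_px & !in_lum
        if (gap[i, s]) {
          ang <- (atan2(pc - q[2], pr - q[1]) * 180 / pi) %% 360
          da <- (ang - a0) %% 360
          in_mye[da < cf$gap_arc] <- FALSE  # arc reverts to background
        }
        list(lum = in_lum, mye = in_mye)
      }
      # intensity: subpixel coverage average (optical softness); label: centre
      off <- if (cf$antialias) c(-1, 0, 1) / 3 else 0
      acc <- matrix(0, length(rr), length(cc))
      for (o1 in off) for (o2 in off) {
        cl <- classify(gr + o1, gc + o2)
        acc <- acc + ifelse(cl$lum, cf$lumen_level,
                            ifelse(cl$mye, cf$myelin_level,
                                   cf$background_level))
      }
      acc <- acc / length(off)^2
      ctr <- classify(gr, gc)
      touched <- ctr$lum | ctr$mye | acc != cf$background_level
      sub <- img[rr, cc]
      sub[touched] <- acc[touched]
      img[rr, cc] <- sub
      lsub <- lab[rr, cc]
      lsub[ctr$lum] <- i
      lab[rr, cc] <- lsub
      area_px[i] <- sum(ctr$lum)
    }
    rec[[s]] <- data.frame(axon_id = axon_name(seq_len(n)), slice = s,
                           row_um = cr_um, col_um = cc_um,
                           area_um2 = pi * r_lumen^2 * jit[, s],
                           area_px = area_px,
                           gap = gap[, s], gap_angle_deg = gap_angle[, s])
    labels[[s]] <- lab
    slices[[s]] <- img
  }
  if (cf$noise_sd > 0)
    slices <- lapply(slices, function(m)
      matrix(pmin(pmax(round(m + rnorm(length(m), 0, cf$noise_sd)), 0), 255),
             nrow(m), ncol(m)))
  axons <- data.frame(axon_id = axon_name(seq_len(n)),
                      diameter_um = d, r_out_um = r_out,
                      row0_um = ctr0[, 1] + cen_um[1],
                      col0_um = ctr0[, 2] + cen_um[2],
                      dist_center_um = dist0,
                      gap_probability = gp)
  truth <- list(axons = axons, axon_slices = do.call(rbind, rec),
                transforms = tf, nerve_radius_um = R_nerve)
  structure(list(stack = image_stack(slices, cal), labels = labels,
                 truth = truth, config = cf),
            class = "nerve_phantom")
}

#' @export
print.nerve_phantom <- function(x, ...) {
  cat(sprintf("nerve_phantom: %d axons, %d slices, %d x %d px, %.3g um/px\n",
              x$config$n_axons, x$config$n_slices,
              x$config$image_size[1], x$config$image_size[2],
              x$config$xy_scale))
  invisible(x)
}

# stable zero-padded axon names ("axon001", ...), sortable as text
axon_name <- function(i) sprintf("axon%03d", i)

#' Subsample a stack along z
#'
#' Keeps slices `1, 1+step, 1+2*step, ...`, emulating segmentation with a
#' larger inter-slice interval (every second or third section); the z step of
#' the calibration is multiplied accordingly.
#'
#' @param stack An `image_stack`.
#' @param step Positive integer subsampling step.
#' @return The subsampled `image_stack`.
#' @examples
#' ph <- generate_phantom(phantom_config(n_axons = 2, n_slices = 32,
#'                                       image_size = c(64, 64)))
#' length(subsample_stack(ph$stack, 3)) # 11
#' @export
subsample_stack <- function(stack, step) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(step) || length(step) != 1 || step < 1 || step %% 1 != 0)
    stop("step must be a positive integer")
  keep <- seq(1, length(stack$slices), by = step)
  cal <- stack$calibration
  out <- image_stack(stack$slices[keep],
                     calibration(cal$xy_scale, cal$z_step * step,
                                 cal$shrinkage_factor))
  attr(out, "kept_slices") <- keep
  out
}
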