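#' Segmentation parameters for seeded region growing
#'
#' Mirrors the stop criteria of interactive region-growing tracing: growth
#' stops at pixels whose brightness differs from the seed pixel by more than
#' `brightness_tol`; traced contours are smoothed with a circular moving
#' average; slice-to-slice propagation aborts when the region area changes
#' by at least `area_change_stop` of the previous area. The hue and
#' saturation tolerances are kept for completeness but are inert on 8-bit
#' grayscale input, which is the intended working format.
#'
#' @param hue_tol,sat_tol Hue/saturation stop tolerances (8-bit units);
#'   unused on grayscale images.
#' @param brightness_tol Brightness stop tolerance (8-bit units).
#' @param smooth_window Contour moving-average window length; 1 (identity)
#'   or an odd integer >= 3.
#' @param area_change_stop Fractional area change between consecutive slices
#'   at which propagation aborts (in `(0, 1]`); the default 0.99 aborts when
#'   the region roughly doubles (a leak through an open boundary) or
#'   collapses.
#' @param min_region_px Minimum usable region size in pixels.
#' @param manual_circle_radius_um Radius of the manual fallback circle, µm.
#' @return An object of class `"segmentation_config"`.
#' @export
segmentation_config <- function(hue_tol = 50, sat_tol = 50,
                                brightness_tol = 20, smooth_window = 7,
                                area_change_stop = 0.99, min_region_px = 4,
                                manual_circle_radius_um = 0.5) {
  stopifnot(hue_tol >= 0, sat_tol >= 0, brightness_tol >= 0,
            smooth_window >= 1,
            smooth_window == 1 || (smooth_window %% 2 == 1 && smooth_window >= 3),
            area_change_stop > 0, area_change_stop <= 1,
            min_region_px >= 1, manual_circle_radius_um > 0)
  structure(list(hue_tol = hue_tol, sat_tol = sat_tol,
                 brightness_tol = brightness_tol,
                 smooth_window = as.integer(smooth_window),
                 area_change_stop = area_change_stop,
                 min_region_px = as.integer(min_region_px),
                 manual_circle_radius_um = manual_circle_radius_um),
            class = "segmentation_config")
}

#' Seeded region growing within one slice
#'
#' Grows a 4-connected region from the seed pixel over all pixels whose
#' intensity differs from the seed pixel's intensity by at most
#' `brightness_tol`. This is the per-slice "wildfire" fill.
#'
#' @param img Numeric matrix (8-bit grayscale slice).
#' @param seed Integer `c(row, col)` of the seeding point (1-based).
#' @param config A [segmentation_config()].
#' @return An object of class `"wildfire_region"`: list with `mask` (logical
#'   matrix), `area_px`, `touches_border`, `seed`, `seed_intensity` and
#'   `status` (`"ok"` or `"too_small"`).
#' @export
wildfire_fill <- function(img, seed, config = segmentation_config()) {
  stopifnot(is.matrix(img), length(seed) == 2)
  seed <- as.integer(round(seed))
  if (seed[1] < 1 || seed[1] > nrow(img) || seed[2] < 1 || seed[2] > ncol(img))
    stop("seed outside image")
  mask <- .wildfire_fill_cpp(img, seed[1], seed[2], config$brightness_tol)
  area <- sum(mask)
  tb <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  structure(list(mask = mask, area_px = area, touches_border = tb,
                 seed = seed, seed_intensity = img[seed[1], seed[2]],
                 status = if (area < config$min_region_px) "too_small" else "ok"),
            class = "wildfire_region")
}

# circular moving average of polygon vertex coordinates
smooth_closed <- function(xy, window) {
  if (window <= 1 || nrow(xy) <= window) return(xy)
  k <- rep(1 / window, window)
  cbind(as.numeric(stats::filter(xy[, 1], k, circular = TRUE)),
        as.numeric(stats::filter(xy[, 2], k, circular = TRUE)))
}

#' Extract and smooth the outer contour of a region
#'
#' Follows the region's outer boundary as the 0.5-level iso-contour of the
#' binary mask (marching squares), which tracks the pixel-boundary crack and
#' therefore preserves the pixel-counted area, then applies a circular
#' moving average of length `smooth_window` to the vertex coordinates. If
#' smoothing would make the polygon self-intersecting (possible for very
#' thin regions), the unsmoothed boundary is kept. Interior holes (single
#' excluded noise pixels) are ignored: only the largest boundary loop is
#' returned.
#'
#' @param region A `"wildfire_region"` (or a logical mask matrix).
#' @param config A [segmentation_config()]; supplies `smooth_window` and
#'   `min_region_px`.
#' @param cal A [calibration()]; vertices are returned in µm.
#' @param slice_index Slice the contour belongs to.
#' @param source `"grown"` or `"manual_circle"`.
#' @return An object of class `"axon_contour"`: list with `slice`,
#'   `vertices` (n x 2 matrix, µm, columns `row_um`, `col_um`), `source`,
#'   `area_px` and `border_open` (TRUE when the region touched the image
#'   border).
#' @export
region_to_contour <- function(region, config = segmentation_config(),
                              cal = calibration(1, 1), slice_index = 1L,
                              source = "grown") {
  if (is.matrix(region) && is.logical(region))
    region <- structure(list(mask = region, area_px = sum(region),
                             touches_border = any(region[1, ]) ||
                               any(region[nrow(region), ]) ||
                               any(region[, 1]) || any(region[, ncol(region)]),
                             status = if (sum(region) < config$min_region_px)
                               "too_small" else "ok"),
                        class = "wildfire_region")
  if (region$area_px < max(config$min_region_px, 3))
    stop("region too small for a contour (too_small)")
  d <- dim(region$mask)
  pad <- matrix(0, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- region$mask
  loops <- grDevices::contourLines(seq_len(d[1] + 2), seq_len(d[2] + 2),
                                   pad, levels = 0.5)
  if (!length(loops)) stop("region has no traceable boundary")
  loop_area <- vapply(loops, function(l) {
    x <- l$x; y <- l$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  lp <- loops[[which.max(loop_area)]]
  n <- length(lp$x)
  if (lp$x[1] == lp$x[n] && lp$y[1] == lp$y[n]) n <- n - 1  # drop closure
  bpx <- cbind(lp$x[seq_len(n)] - 1, lp$y[seq_len(n)] - 1)  # unpad
  sm <- smooth_closed(bpx, config$smooth_window)
  if (!is_simple_polygon(sm)) sm <- bpx
  scale <- cal$xy_scale * cal$shrinkage_factor
  verts <- cbind(row_um = (sm[, 1] - 0.5) * scale,
                 col_um = (sm[, 2] - 0.5) * scale)
  structure(list(slice = as.integer(slice_index), vertices = verts,
                 source = source, area_px = region$area_px,
                 border_open = region$touches_border),
            class = "axon_contour")
}

#' Manually drawn circular contour
#'
#' Fallback used where region growing cannot fill an axon (too small or too
#' noisy): a regular polygon approximating a circle of the requested radius.
#'
#' @param center_um Circle centre `c(row_um, col_um)` in µm.
#' @param radius_um Radius in µm (> 0).
#' @param slice_index Slice index.
#' @param n_vertices Number of polygon vertices (>= 32).
#' @return An `"axon_contour"` with `source = "manual_circle"`.
#' @examples
#' ct <- manual_circle(c(10, 10), 2, 1)
#' polygon_area(ct) # close to pi * 4
#' @export
manual_circle <- function(center_um, radius_um, slice_index,
                          n_vertices = 64L) {
  stopifnot(radius_um > 0, n_vertices >= 32)
  a <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  verts <- cbind(row_um = center_um[1] + radius_um * cos(a),
                 col_um = center_um[2] + radius_um * sin(a))
  structure(list(slice = as.integer(slice_index), vertices = verts,
                 source = "manual_circle", area_px = NA_real_,
                 border_open = FALSE),
            class = "axon_contour")
}

# centroid of a region mask in pixel coordinates
region_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Propagate an axon trace through the stack
#'
#' Grows the axon on `start_slice` from the given seed, then walks slice by
#' slice: the next seed is the centroid of the previous accepted region
#' (falling back to the previous-region pixel nearest the centroid whose
#' intensity on the new slice is still within `brightness_tol` of the
#' previous seed intensity). A grown region is accepted iff its pixel area
#' changed by less than `area_change_stop` relative to the previous accepted
#' region. On failure an abortion event is recorded — reason `no_seed`
#' (no valid seeding point), `leak` (area explosion / border contact,
#' typically growth through an open myelin boundary), `area_jump` (area
#' collapse) or `too_small` — and the trace halts at that slice, unless the
#' `on_abort` hook supplies a replacement seed (emulating the interactive
#' operator decision), in which case tracing resumes on the same slice; if
#' even the replacement region is unusable, a manual circle of
#' `manual_circle_radius_um` is inserted at the replacement seed.
#'
#' @param stack An `image_stack`.
#' @param axon_id Stable axon name; all contours of the trace carry it.
#' @param seed_px Integer `c(row, col)` seed on `start_slice`.
#' @param start_slice First slice to segment (default 1).
#' @param config A [segmentation_config()].
#' @param on_abort `NULL`, or `function(event)` returning a replacement seed
#'   `c(row, col)` (px, on slice `event$slice`) or `NULL` to halt.
#' @return `list(trace, abortions)`: the `"axon_trace"` (fields `axon_id`,
#'   `contours` — one per traced slice —, `status` `"complete"` or
#'   `"aborted"`) and a data frame of abortion events
#'   `(axon_id, slice, reason)`.
#' @export
propagate_trace <- function(stack, axon_id, seed_px, start_slice = 1L,
                            config = segmentation_config(), on_abort = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$slices)
  if (start_slice < 1 || start_slice > n) stop("start_slice outside stack")
  cal <- stack$calibration
  events <- list()
  contours <- list()
  abort <- function(slice, reason) {
    events[[length(events) + 1]] <<- data.frame(axon_id = axon_id,
                                                slice = slice, reason = reason)
    if (is.null(on_abort)) return(NULL)
    on_abort(list(axon_id = axon_id, slice = slice, reason = reason))
  }
  prev_area <- NA_real_
  prev_mask <- NULL
  prev_seed_int <- NA_real_
  seed <- as.integer(round(seed_px))
  halted <- FALSE
  for (s in seq(start_slice, n)) {
    img <- stack$slices[[s]]
    if (s > start_slice) {
      cen <- round(region_centroid(prev_mask))
      cen[1] <- min(max(cen[1], 1), nrow(img))
      cen[2] <- min(max(cen[2], 1), ncol(img))
      if (abs(img[cen[1], cen[2]] - prev_seed_int) <= config$brightness_tol) {
        seed <- cen
      } else {
        # nearest previous-region pixel that is still bright on this slice
        idx <- which(prev_mask, arr.ind = TRUE)
        dd <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
        ord <- order(dd)
        ok <- abs(img[idx[ord, , drop = FALSE]] - prev_seed_int) <=
          config$brightness_tol
        if (!any(ok)) {
          rs <- abort(s, "no_seed")
          if (is.null(rs)) { halted <- TRUE; break }
          seed <- as.integer(round(rs))
        } else seed <- as.integer(idx[ord[which(ok)[1]], ])
      }
    }
    reg <- wildfire_fill(img, seed, config)
    accept <- TRUE
    reason <- NULL
    if (reg$status == "too_small") {
      accept <- FALSE
      reason <- if (s == start_slice) "no_seed" else "too_small"
    } else if (!is.na(prev_area)) {
      rel <- abs(reg$area_px - prev_area) / prev_area
      if (rel >= config$area_change_stop) {
        accept <- FALSE
        reason <- if (reg$area_px > prev_area) "leak" else "area_jump"
      }
    }
    if (!accept) {
      rs <- abort(s, reason)
      if (is.null(rs)) { halted <- TRUE; break }
      seed2 <- as.integer(round(rs))
      reg2 <- wildfire_fill(img, seed2, config)
      # the replacement is the operator's judgement: accept the regrown
      # region unless it is unusable or leaks again on the same slice
      regrown_ok <- reg2$status == "ok" && !reg2$touches_border &&
        (is.na(prev_area) ||
         reg2$area_px < (1 + config$area_change_stop) * prev_area)
      if (regrown_ok) {
        reg <- reg2
        seed <- seed2
      } else {
        # operator fallback: a circle congruent with the previous accepted
        # cross-section (or the configured radius when there is none)
        scale <- cal$xy_scale * cal$shrinkage_factor
        r_um <- if (is.na(prev_area)) config$manual_circle_radius_um
                else max(sqrt(prev_area / pi) * scale,
                         config$manual_circle_radius_um)
        ctr_um <- (seed2 - 0.5) * scale
        ct <- manual_circle(ctr_um, r_um, s)
        ct$area_px <- pi * (r_um / scale)^2
        contours[[length(contours) + 1]] <- ct
        prev_area <- ct$area_px
        # circle footprint as the propagation mask for the next seed search
        r_px <- r_um / scale
        rr <- max(1, floor(seed2[1] - r_px)):min(nrow(img), ceiling(seed2[1] + r_px))
        ccx <- max(1, floor(seed2[2] - r_px)):min(ncol(img), ceiling(seed2[2] + r_px))
        pm <- matrix(FALSE, nrow(img), ncol(img))
        pm[rr, ccx] <- outer(rr, ccx, function(a, b)
          (a - seed2[1])^2 + (b - seed2[2])^2 <= r_px^2)
        if (!any(pm)) pm[seed2[1], seed2[2]] <- TRUE
        prev_mask <- pm
        prev_seed_int <- img[seed2[1], seed2[2]]
        next
      }
    }
    ct <- region_to_contour(reg, config, cal, s)
    contours[[length(contours) + 1]] <- ct
    prev_area <- reg$area_px
    prev_mask <- reg$mask
    prev_seed_int <- reg$seed_intensity
  }
  trace <- structure(list(axon_id = axon_id, contours = contours,
                          status = if (halted) "aborted" else "complete",
                          start_slice = as.integer(start_slice)),
                     class = "axon_trace")
  abortions <- if (length(events)) do.call(rbind, events) else
    data.frame(axon_id = character(), slice = integer(), reason = character())
  list(trace = trace, abortions = abortions)
}

#' @export
print.axon_trace <- function(x, ...) {
  sl <- vapply(x$contours, `[[`, integer(1), "slice")
  cat(sprintf("axon_trace %s: %d contours (slices %s-%s), status %s\n",
              x$axon_id, length(x$contours),
              if (length(sl)) min(sl) else NA, if (length(sl)) max(sl) else NA,
              x$status))
  invisible(x)
}

#' Segment many axons through a stack
#'
#' Runs [propagate_trace()] for every seeded axon, in ascending `axon_id`
#' order, pooling the abortion log.
#'
#' @param stack An `image_stack`.
#' @param seeds Data frame with columns `axon_id`, `row_px`, `col_px` (seeds
#'   on the first slice).
#' @param config A [segmentation_config()].
#' @param on_abort Optional replacement-seed hook, `function(event)`; see
#'   [propagate_trace()].
#' @return `list(traces, abortions)`: named list of `"axon_trace"` objects
#'   and the pooled abortion data frame.
#' @export
segment_stack <- function(stack, seeds, config = segmentation_config(),
                          on_abort = NULL) {
  stopifnot(all(c("axon_id", "row_px", "col_px") %in% names(seeds)))
  seeds <- seeds[order(seeds$axon_id), ]
  traces <- list()
  logs <- list()
  for (i in seq_len(nrow(seeds))) {
    res <- propagate_trace(stack, seeds$axon_id[i],
                           c(seeds$row_px[i], seeds$col_px[i]),
                           start_slice = 1L, config = config,
                           on_abort = on_abort)
    traces[[seeds$axon_id[i]]] <- res$trace
    logs[[i]] <- res$abortions
  }
  list(traces = traces, abortions = do.call(rbind, logs))
}

#' Serialize traces to CSV plus a JSON index
#'
#' Writes one CSV per axon (`slice, vertex, row_um, col_um, source`) and a
#' JSON index mapping each axon to its slice range and status; the abortion
#' log is written as a separate CSV.
#'
#' @param traces Named list of `"axon_trace"` objects.
#' @param abortions Abortion data frame (may be empty).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the index file path.
#' @export
write_traces <- function(traces, abortions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  index <- list()
  for (id in names(traces)) {
    tr <- traces[[id]]
    rows <- lapply(tr$contours, function(ct)
      data.frame(slice = ct$slice, vertex = seq_len(nrow(ct$vertices)),
                 row_um = ct$vertices[, 1], col_um = ct$vertices[, 2],
                 source = ct$source))
    df <- do.call(rbind, rows)
    write.csv(df, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
    sl <- vapply(tr$contours, `[[`, integer(1), "slice")
    index[[id]] <- list(first_slice = min(sl), last_slice = max(sl),
                        status = tr$status)
  }
  jsonlite::write_json(index, file.path(dir, "traces_index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write.csv(abortions, file.path(dir, "abortions.csv"), row.names = FALSE)
  invisible(file.path(dir, "traces_index.json"))
}

#' Read traces written by [write_traces()]
#'
#' @param dir Directory containing per-axon CSVs and `traces_index.json`.
#' @return Named list of `"axon_trace"` objects.
#' @export
read_traces <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "traces_index.json"))
  traces <- list()
  for (id in names(index)) {
    df <- read.csv(file.path(dir, paste0(id, ".csv")))
    contours <- lapply(split(df, df$slice), function(g)
      structure(list(slice = g$slice[1],
                     vertices = cbind(row_um = g$row_um, col_um = g$col_um),
                     source = g$source[1], area_px = NA_real_,
                     border_open = FALSE),
                class = "axon_contour"))
    contours <- contours[order(as.integer(names(contours)))]
    traces[[id]] <- structure(list(axon_id = id, contours = unname(contours),
                                   status = index[[id]]$status,
                                   start_slice = index[[id]]$first_slice),
                              class = "axon_trace")
  }
  traces
}
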