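# ---- polygon geometry ------------------------------------------------------

# strictly proper segment-crossing test over all non-adjacent segment pairs
#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' @param xy n x 2 matrix of vertices (closed implicitly).
#' @return `TRUE` if no two non-adjacent edges properly cross.
#' @export
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  p <- xy
  q <- xy[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)]  # skip wrap-around adjacency
    if (!length(j)) next
    d1 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], p[j, 1], p[j, 2])
    d2 <- cross(p[i, 1], p[i, 2], q[i, 1], q[i, 2], q[j, 1], q[j, 2])
    d3 <- cross(p[j, 1], p[j, 2], q[j, 1], q[j, 2], rep(p[i, 1], length(j)),
                rep(p[i, 2], length(j)))
    d4 <- cross(p[j, 1], p[j, 2], q[j, 1], q[j, 2], rep(q[i, 1], length(j)),
                rep(q[i, 2], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Area of a traced contour (shoelace formula)
#'
#' Orientation-independent (absolute) polygon area. For an `"axon_contour"`
#' the vertices are already in µm, so the area is in µm².
#'
#' @param contour An `"axon_contour"` or an n x 2 vertex matrix.
#' @param check If `TRUE`, error on self-intersecting polygons.
#' @return Area (µm² for calibrated contours).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # 1
#' @export
polygon_area <- function(contour, check = TRUE) {
  xy <- if (inherits(contour, "axon_contour")) contour$vertices else contour
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3)
  if (check && !is_simple_polygon(xy)) stop("polygon is self-intersecting")
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Centroid of a simple polygon
#'
#' @param contour An `"axon_contour"` or an n x 2 vertex matrix.
#' @return Length-2 centroid (same units as the vertices).
#' @export
polygon_centroid <- function(contour) {
  xy <- if (inherits(contour, "axon_contour")) contour$vertices else contour
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# ---- scalar morphometry ----------------------------------------------------

#' Idealized axon diameter from the inner cross-sectional area
#'
#' Diameter of the circle with the same area as the (possibly oval) measured
#' inner cross-section: `2 * sqrt(area / pi)`.
#'
#' @param area Inner cross-sectional area, µm² (> 0).
#' @return Diameter, µm.
#' @examples
#' idealized_diameter(12.57) # about 4 um
#' @export
idealized_diameter <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' @rdname idealized_diameter
#' @param diameter Idealized diameter, µm (> 0).
#' @export
idealized_area <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  pi * (diameter / 2)^2
}

#' Outer fiber diameter from the inner diameter and g-ratio
#'
#' The g-ratio is the ratio of inner (axon) to outer (fiber including
#' myelin) diameter, so `outer = inner / g`.
#'
#' @param inner_diameter Inner (axonal) diameter, µm.
#' @param g_ratio g-ratio, strictly in (0, 1).
#' @return Outer diameter, µm.
#' @export
outer_diameter <- function(inner_diameter, g_ratio) {
  if (any(g_ratio <= 0) || any(g_ratio >= 1))
    stop("g_ratio must lie strictly between 0 and 1")
  inner_diameter / g_ratio
}

#' Abortions per axon per slice
#'
#' The segmentation-quality rate: total abortion events divided by
#' (axons x slices), reported by default to 2 significant figures.
#'
#' @param n_abortions Total abortion events (>= 0).
#' @param n_axons,n_slices Positive counts.
#' @param signif_digits Significant digits for reporting (`NULL` for full
#'   precision).
#' @return Abortions per axon per slice.
#' @examples
#' abortion_rate(207, 120, 32) # 0.054
#' @export
abortion_rate <- function(n_abortions, n_axons, n_slices, signif_digits = 2) {
  if (n_axons <= 0 || n_slices <= 0) stop("axon and slice counts must be > 0")
  if (n_abortions < 0) stop("abortion count cannot be negative")
  r <- n_abortions / (n_axons * n_slices)
  if (is.null(signif_digits)) r else signif(r, signif_digits)
}

# ---- per-axon records ------------------------------------------------------

#' Build per-axon morphometry records from traces
#'
#' Computes per-slice inner areas (shoelace, µm²) and centroids for every
#' trace, the per-axon mean area and idealized diameter, the abortion count,
#' and each axon's mean distance to the nerve centre. The nerve centre of a
#' slice is the centroid of all axon centroids on that slice.
#'
#' @param traces Named list of `"axon_trace"` objects.
#' @param abortions Abortion event data frame (`axon_id, slice, reason`), or
#'   `NULL`.
#' @return List with `per_slice` (axon_id, slice, area_um2, row_um, col_um)
#'   and `axons` (axon_id, n_slices, mean_area_um2, idealized_diameter_um,
#'   dist_center_um, abortion_count).
#' @export
axon_records <- function(traces, abortions = NULL) {
  per <- lapply(traces, function(tr) {
    rows <- lapply(tr$contours, function(ct) {
      cen <- polygon_centroid(ct)
      data.frame(axon_id = tr$axon_id, slice = ct$slice,
                 area_um2 = polygon_area(ct, check = FALSE),
                 row_um = cen[1], col_um = cen[2])
    })
    do.call(rbind, rows)
  })
  per_slice <- do.call(rbind, per)
  rownames(per_slice) <- NULL
  # per-slice nerve centre = centroid of axon centroids
  ctr <- aggregate(cbind(row_um, col_um) ~ slice, per_slice, mean)
  names(ctr)[2:3] <- c("nerve_row_um", "nerve_col_um")
  m <- merge(per_slice, ctr, by = "slice")
  m$dist <- sqrt((m$row_um - m$nerve_row_um)^2 +
                 (m$col_um - m$nerve_col_um)^2)
  ax <- do.call(rbind, lapply(split(m, m$axon_id), function(g)
    data.frame(axon_id = g$axon_id[1], n_slices = nrow(g),
               mean_area_um2 = mean(g$area_um2),
               dist_center_um = mean(g$dist))))
  ax$idealized_diameter_um <- idealized_diameter(ax$mean_area_um2)
  ab <- if (is.null(abortions) || !nrow(abortions))
    integer(nrow(ax))
  else as.integer(table(factor(abortions$axon_id, levels = ax$axon_id)))
  ax$abortion_count <- ab
  rownames(ax) <- NULL
  list(per_slice = per_slice, axons = ax[order(ax$axon_id), ])
}

#' Per-slice percentage deviation from each axon's mean area
#'
#' The per-axon mean inner area is set to 100 % and every slice's area is
#' expressed as a percentage deviation from it, removing the quadratic size
#' dependence before comparing fluctuation across size classes. The
#' deviations of each axon average to zero exactly.
#'
#' @param x Numeric vector of one axon's per-slice areas (>= 2 slices), or
#'   the `per_slice` data frame from [axon_records()] (grouped by axon).
#' @return Numeric deviations (%) or, for a data frame input, the data frame
#'   with a `deviation_pct` column added.
#' @examples
#' normalize_fluctuation(c(90, 110)) # -10, +10
#' @export
normalize_fluctuation <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("axon_id", "area_um2") %in% names(x)))
    dev <- unlist(lapply(split(x$area_um2, x$axon_id), function(a)
      100 * (a - mean(a)) / mean(a)), use.names = FALSE)
    ord <- order(x$axon_id)
    x$deviation_pct[ord] <- dev
    return(x)
  }
  stopifnot(is.numeric(x), length(x) >= 2)
  100 * (x - mean(x)) / mean(x)
}

#' Split axons into equally sized diameter classes
#'
#' Sorts axons by idealized diameter (ties broken by `axon_id`) and splits
#' them into `k` contiguous classes of identical size, reporting each
#' class's diameter interval.
#'
#' @param axons The `axons` data frame from [axon_records()] (needs
#'   `axon_id` and `idealized_diameter_um`).
#' @param k Number of classes; `nrow(axons)` must be divisible by `k`.
#' @return List with `membership` (axon_id, class) and `classes` (class, n,
#'   d_min_um, d_max_um); classes are labelled `"A"`, `"B"`, ... from the
#'   smallest diameters up.
#' @export
group_equal_n <- function(axons, k) {
  n <- nrow(axons)
  if (k < 2) stop("need at least 2 classes")
  if (n %% k != 0)
    stop(sprintf("number of axons (%d) is not divisible by k = %d", n, k))
  ord <- order(axons$idealized_diameter_um, axons$axon_id)
  per <- n / k
  cls <- rep(LETTERS[seq_len(k)], each = per)
  membership <- data.frame(axon_id = axons$axon_id[ord], class = cls)
  d <- axons$idealized_diameter_um[ord]
  classes <- data.frame(class = LETTERS[seq_len(k)], n = per,
                        d_min_um = tapply(d, cls, min),
                        d_max_um = tapply(d, cls, max))
  rownames(classes) <- NULL
  list(membership = membership, classes = classes)
}

#' Compare area fluctuation across diameter classes
#'
#' Pools each class's per-slice percentage deviations and runs a
#' Kruskal-Wallis rank test across all classes plus the full matrix of
#' pairwise Welch (unequal-variance) t-tests.
#'
#' @param grouping Result of [group_equal_n()].
#' @param deviations Data frame with `axon_id` and `deviation_pct` (e.g.
#'   [normalize_fluctuation()] applied to the `per_slice` records).
#' @param two_sided Welch tests are two-sided by default.
#' @return List with `kruskal` (`statistic`, `df`, `p.value`), `welch_p`
#'   (k x k matrix of p-values), and `class_summary` (class, n_points, sd).
#' @export
class_tests <- function(grouping, deviations, two_sided = TRUE) {
  stopifnot(all(c("axon_id", "deviation_pct") %in% names(deviations)))
  m <- merge(deviations, grouping$membership, by = "axon_id")
  groups <- split(m$deviation_pct, m$class)
  if (length(groups) < 2) stop("need at least 2 classes")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every class needs at least 2 pooled data points")
  kw <- kruskal.test(groups)
  k <- length(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tt <- t.test(groups[[i]], groups[[j]], var.equal = FALSE,
                 alternative = if (two_sided) "two.sided" else "less")
    pmat[i, j] <- pmat[j, i] <- tt$p.value
  }
  summ <- data.frame(class = names(groups),
                     n_points = vapply(groups, length, integer(1)),
                     sd = vapply(groups, sd, numeric(1)))
  rownames(summ) <- NULL
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value),
       welch_p = pmat, class_summary = summ)
}

#' Abortions versus axon size: decay fit and rank correlation
#'
#' Abortion counts concentrate in small axons; this fits a one-phase
#' exponential decay `y = plateau + A * exp(-lambda * d)` to abortions over
#' idealized diameter (reporting the decay constant `lambda` and its
#' length-scale `tau = 1/lambda`), and quantifies the monotone association
#' with Spearman's rank correlation (expected negative).
#'
#' @param abortions_per_axon Numeric abortion counts, one per axon.
#' @param diameters Idealized diameters, µm (same length, with variation).
#' @return List with `fit` (`plateau`, `amplitude`, `lambda`, `tau`) and
#'   `spearman` (`r`, `p.value`).
#' @export
size_effect <- function(abortions_per_axon, diameters) {
  y <- abortions_per_axon; x <- diameters
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 axons")
  if (diff(range(x)) == 0) stop("diameters are degenerate (all equal)")
  st <- cor.test(x, y, method = "spearman", exact = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- NULL
  for (l0 in c(1, 0.3, 3, 1 / max(mean(x), 1e-6))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ plateau + A * exp(-lambda * x), data = df,
                        start = list(plateau = min(y),
                                     A = max(max(y) - min(y), 1e-3),
                                     lambda = l0),
                        lower = c(-Inf, 0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("one-phase decay fit failed to converge")
  cf <- coef(fit)
  list(fit = list(plateau = unname(cf["plateau"]),
                  amplitude = unname(cf["A"]),
                  lambda = unname(cf["lambda"]),
                  tau = 1 / unname(cf["lambda"])),
       spearman = list(r = unname(st$estimate), p.value = st$p.value))
}

#' Axon position effects: size bias check and abortion regression
#'
#' Tests (a) whether axon size correlates with distance from the nerve
#' centre (a potential confounder; Spearman correlation and a linear
#' regression of diameter on distance), and (b) whether the abortion count
#' increases with distance from the centre (linear regression slope and
#' two-sided p-value).
#'
#' @param axons The `axons` data frame from [axon_records()] (needs
#'   `idealized_diameter_um`, `dist_center_um`, `abortion_count`).
#' @return List with `size_vs_distance` (`spearman_r`, `spearman_p`,
#'   `r_squared`, `slope`, `slope_p`) and `abortion_vs_distance` (`slope`,
#'   `slope_p`, `r_squared`).
#' @export
position_effect <- function(axons) {
  if (nrow(axons) < 3) stop("need at least 3 axons")
  d <- axons$dist_center_um
  if (diff(range(d)) == 0) stop("all axons at one distance: regression undefined")
  st <- cor.test(d, axons$idealized_diameter_um, method = "spearman",
                 exact = FALSE)
  f1 <- lm(idealized_diameter_um ~ dist_center_um, data = axons)
  s1 <- summary(f1)
  f2 <- lm(abortion_count ~ dist_center_um, data = axons)
  s2 <- summary(f2)
  list(size_vs_distance = list(spearman_r = unname(st$estimate),
                               spearman_p = st$p.value,
                               r_squared = s1$r.squared,
                               slope = unname(coef(f1)[2]),
                               slope_p = s1$coefficients[2, 4]),
       abortion_vs_distance = list(slope = unname(coef(f2)[2]),
                                   slope_p = s2$coefficients[2, 4],
                                   r_squared = s2$r.squared))
}
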