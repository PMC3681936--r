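test_that("polygon area and centroid follow the shoelace formula", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  # 64-gon of radius 2: regular-polygon closed form (pi * 4 * cos-correction)
  n <- 64
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  poly <- cbind(2 * cos(a), 2 * sin(a))
  expect_equal(polygon_area(poly), 0.5 * n * 4 * sin(2 * pi / n))
  expect_equal(polygon_area(poly), 12.55, tolerance = 1e-2)
  # rigid invariance
  th <- 0.7
  rot <- cbind(cos(th) * poly[, 1] - sin(th) * poly[, 2] + 5,
               sin(th) * poly[, 1] + cos(th) * poly[, 2] - 3)
  expect_equal(polygon_area(rot), polygon_area(poly), tolerance = 1e-12)
  expect_equal(polygon_centroid(rot), c(5, -3), tolerance = 1e-9)
  # orientation independence
  expect_equal(polygon_area(poly[n:1, ]), polygon_area(poly))
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("idealized diameter is the equal-area circle diameter", {
  expect_equal(idealized_diameter(12.57), 4.0, tolerance = 1e-3)
  expect_equal(idealized_diameter(pi), 2.0)
  a <- c(0.37, 12.57, 113.1)
  expect_equal(idealized_area(idealized_diameter(a)), a, tolerance = 1e-12)
  expect_true(all(diff(idealized_diameter(c(1, 2, 5, 20))) > 0))
  expect_error(idealized_diameter(0), "positive")
  expect_error(idealized_area(-1), "positive")
})

test_that("outer diameter scales the inner diameter by 1/g", {
  expect_equal(outer_diameter(4.0, 0.6), 6.67, tolerance = 1e-3)
  expect_equal(outer_diameter(4.0, 0.999), 4.0, tolerance = 5e-3)
  g <- c(0.3, 0.5, 0.7, 0.9)
  expect_true(all(diff(outer_diameter(4, g)) < 0))
  expect_error(outer_diameter(4, 1), "between 0 and 1")
  expect_error(outer_diameter(4, 0), "between 0 and 1")
})

test_that("abortion rate reproduces the printed worked examples", {
  expect_equal(abortion_rate(207, 120, 32), 0.054)
  expect_equal(abortion_rate(277, 120, 16), 0.14)
  expect_equal(abortion_rate(300, 120, 11), 0.23)
  expect_equal(abortion_rate(0, 120, 32), 0)
  expect_error(abortion_rate(5, 0, 32), "> 0")
})

test_that("fluctuation normalization centres every axon at zero", {
  expect_equal(normalize_fluctuation(c(50, 50, 50)), c(0, 0, 0))
  expect_equal(normalize_fluctuation(c(90, 110)), c(-10, 10))
  set.seed(33)
  for (rep in 1:10) {
    a <- rlnorm(32, 2, 0.3)
    d <- normalize_fluctuation(a)
    expect_lt(abs(mean(d)), 1e-9 * mean(abs(d)))
  }
  # pooled SD matches the generator CV at scale (Monte-Carlo over 120 axons)
  set.seed(7)
  cv <- 0.1
  sdl <- sqrt(log(1 + cv^2))
  pooled <- unlist(lapply(1:120, function(i) {
    a <- 20 * rlnorm(32, -sdl^2 / 2, sdl)
    normalize_fluctuation(a)
  }))
  expect_equal(sd(pooled) / 100, cv, tolerance = 0.05)
})

test_that("equal-N grouping splits sorted diameters into contiguous classes", {
  ax <- data.frame(axon_id = sprintf("axon%03d", 1:120),
                   idealized_diameter_um = exp(runif(120, 0.1, 1.8)))
  g <- group_equal_n(ax, 5)
  expect_equal(nrow(g$membership), 120)
  expect_equal(as.integer(table(g$membership$class)), rep(24L, 5))
  expect_true(all(diff(g$classes$d_min_um) > 0))
  # non-overlapping ordered intervals
  expect_true(all(g$classes$d_max_um[-5] <= g$classes$d_min_um[-1]))
  expect_error(group_equal_n(ax[1:100, ], 3), "not divisible")
  # deterministic tie-break on identical diameters
  tie <- data.frame(axon_id = sprintf("axon%03d", 10:1),
                    idealized_diameter_um = rep(1, 10))
  g1 <- group_equal_n(tie, 2)
  g2 <- group_equal_n(tie[sample(10), ], 2)
  expect_equal(g1$membership, g2$membership)
})

test_that("class tests detect size-dependent fluctuation and not its absence", {
  set.seed(91)
  # lognormal area jitter with CV decreasing in size class, at paper-like
  # pooled N (24 x 32 per class); the skewed jitter shifts class medians,
  # which is what the rank test responds to
  mk <- function(cvs) {
    dev <- list(); mem <- list()
    for (k in 1:5) for (i in 1:24) {
      id <- sprintf("ax%d_%02d", k, i)
      sdl <- sqrt(log(1 + cvs[k]^2))
      a <- rlnorm(32, -sdl^2 / 2, sdl)
      dev[[id]] <- data.frame(axon_id = id,
                              deviation_pct = 100 * (a - mean(a)) / mean(a))
      mem[[id]] <- data.frame(axon_id = id, class = LETTERS[k])
    }
    list(dev = do.call(rbind, dev),
         grp = list(membership = do.call(rbind, mem)))
  }
  x <- mk(c(0.35, 0.22, 0.14, 0.08, 0.04))
  ct <- class_tests(x$grp, x$dev)
  expect_lt(ct$kruskal$p.value, 0.01)
  expect_equal(dim(ct$welch_p), c(5, 5))
  expect_equal(sum(x$dev$axon_id %in% x$grp$membership$axon_id), 5 * 24 * 32)
  # two identical samples give Welch p = 1 (t = 0)
  same <- data.frame(axon_id = rep(c("a", "b"), each = 20),
                     deviation_pct = rep(rnorm(20), 2))
  grp2 <- list(membership = data.frame(axon_id = c("a", "b"),
                                       class = c("A", "B")))
  ct2 <- class_tests(grp2, same)
  expect_equal(ct2$welch_p["A", "B"], 1)
  expect_error(class_tests(list(membership = data.frame(axon_id = "a",
                                                        class = "A")),
                           same[same$axon_id == "a", ][1, , drop = FALSE]),
               "at least 2")
})

test_that("size effect recovers decay parameters and ranks", {
  # abortion burden sampled from a known one-phase decay with 10%
  # multiplicative noise over the observed caliber range
  set.seed(42)
  d <- exp(runif(120, log(1.14), log(6.04)))
  y <- 8 * exp(-1.2 * d) * exp(rnorm(120, 0, 0.1))
  se <- size_effect(y, d)
  expect_lt(abs(se$fit$lambda / 1.2 - 1), 0.15)
  expect_equal(se$fit$tau, 1 / se$fit$lambda)
  expect_lt(se$spearman$r, 0)
  # perfectly monotone decreasing counts give r = -1 exactly
  se2 <- size_effect(c(9, 7, 5, 3, 1), c(1, 2, 3, 4, 5))
  expect_equal(se2$spearman$r, -1)
  # shuffled null: mostly insignificant
  set.seed(5)
  hits <- replicate(200, {
    yy <- sample(y)
    ct <- suppressWarnings(cor.test(d, yy, method = "spearman",
                                    exact = FALSE))
    ct$p.value < 0.05
  })
  expect_gte(mean(!hits), 0.9)
  expect_error(size_effect(y, rep(2, 120)), "degenerate")
  expect_error(size_effect(1:3, 1:3), "at least 5")
})

test_that("axon position analyses behave on unbiased and biased phantoms", {
  # generator independence: no size-vs-distance trend on a uniform phantom
  ph <- generate_phantom(phantom_config(seed = 5))
  ax <- ph$truth$axons
  fit <- lm(diameter_um ~ dist_center_um, data = ax)
  sl <- summary(fit)$coefficients[2, ]
  expect_lt(abs(sl["Estimate"]), 2 * sl["Std. Error"] + 1e-9)
  # degenerate inputs
  rec <- data.frame(axon_id = c("a", "b", "c"),
                    idealized_diameter_um = c(1, 2, 3),
                    dist_center_um = c(5, 5, 5), abortion_count = c(0, 1, 2))
  expect_error(position_effect(rec), "one distance")
  expect_error(position_effect(rec[1:2, ]), "at least 3")
})

test_that("radially increasing artifact rates show up as a distance effect", {
  # open-boundary probability grows with distance from the nerve centre;
  # the abortion-vs-distance regression must pick up the positive slope
  # while axon size stays uncorrelated with distance
  cf <- phantom_config(n_slices = 32, diameter_range = c(2, 6),
                       gap_probability = function(d) 0.02 + 0.15 * d,
                       seed = 13)
  ph <- generate_phantom(cf)
  res <- segment_stack(ph$stack, truth_seeds(ph), on_abort = truth_hook(ph))
  rec <- axon_records(res$traces, res$abortions)
  pe <- position_effect(rec$axons)
  expect_gt(pe$abortion_vs_distance$slope, 0)
  expect_lt(pe$abortion_vs_distance$slope_p, 0.05)
  expect_lt(pe$size_vs_distance$r_squared, 0.1)
})
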