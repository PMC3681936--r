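#' Reproducible pipeline configuration
#'
#' Bundles everything one run needs: the phantom (or input stack) settings,
#' segmentation parameters, which inter-slice subsampling steps to evaluate,
#' the number of diameter classes, mesh post-processing settings and the RNG
#' seed. The seed is recorded in every stage manifest so any number in a
#' report can be regenerated from the manifest alone.
#'
#' @param outdir Run directory; every stage reads and writes below it.
#' @param phantom A [phantom_config()].
#' @param segmentation A [segmentation_config()].
#' @param subsample_steps Inter-slice subsampling steps to evaluate.
#' @param k_classes Number of equal-N diameter classes.
#' @param smoothing_iterations HC smoothing passes for meshes.
#' @param decimation_fraction Target vertex fraction for decimation.
#' @param mesh_axons Number of axons to mesh (smallest ids first); keeps the
#'   mesh stage inexpensive on large phantoms.
#' @param seed Run seed; overrides the phantom seed.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(outdir,
                       phantom = phantom_config(),
                       segmentation = segmentation_config(),
                       subsample_steps = c(1, 2, 3),
                       k_classes = 5,
                       smoothing_iterations = 10,
                       decimation_fraction = 0.38,
                       mesh_axons = 12,
                       seed = 1L) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(segmentation, "segmentation_config"),
            all(subsample_steps >= 1), k_classes >= 2,
            smoothing_iterations >= 0,
            decimation_fraction > 0, decimation_fraction < 1,
            mesh_axons >= 1)
  phantom$seed <- as.integer(seed)
  structure(list(outdir = outdir, phantom = phantom,
                 segmentation = segmentation,
                 subsample_steps = as.integer(subsample_steps),
                 k_classes = as.integer(k_classes),
                 smoothing_iterations = as.integer(smoothing_iterations),
                 decimation_fraction = decimation_fraction,
                 mesh_axons = as.integer(mesh_axons),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_for_json <- function(cfg) {
  strip <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(cfg)
}

write_manifest <- function(cfg, stage, inputs, outputs, counts = list()) {
  cfg_json <- jsonlite::toJSON(config_for_json(cfg), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  man <- list(stage = stage, seed = cfg$seed, config_md5 = h,
              inputs = inputs, outputs = outputs, counts = counts)
  p <- file.path(cfg$outdir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(man, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(p)
}

require_file <- function(path) {
  if (!file.exists(path))
    stop("missing required upstream artifact: ", path, call. = FALSE)
  path
}

#' Pipeline stage: simulate a phantom
#'
#' Generates the phantom, writes the image stack as numbered PNGs, the
#' ground truth as CSV and the configuration echo plus a manifest as JSON.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the `"nerve_phantom"`.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  ph <- generate_phantom(cfg$phantom)
  files <- write_stack(ph$stack, file.path(cfg$outdir, "stack"))
  write.csv(ph$truth$axons, file.path(cfg$outdir, "truth_axons.csv"),
            row.names = FALSE)
  write.csv(ph$truth$axon_slices, file.path(cfg$outdir, "truth_slices.csv"),
            row.names = FALSE)
  write.csv(ph$truth$transforms, file.path(cfg$outdir, "truth_transforms.csv"),
            row.names = FALSE)
  jsonlite::write_json(config_for_json(cfg$phantom),
                       file.path(cfg$outdir, "phantom_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg, "simulate",
                 inputs = list(),
                 outputs = list(stack = "stack", truth = "truth_axons.csv"),
                 counts = list(n_axons = cfg$phantom$n_axons,
                               n_slices = cfg$phantom$n_slices))
  invisible(ph)
}

load_run_stack <- function(cfg, prefer_aligned = TRUE) {
  adir <- file.path(cfg$outdir, "stack_aligned")
  sdir <- file.path(cfg$outdir, "stack")
  use <- if (prefer_aligned && dir.exists(adir)) adir else sdir
  require_file(use)
  read_stack(use, calibration(cfg$phantom$xy_scale, cfg$phantom$z_step))
}

#' Pipeline stage: rigid alignment
#'
#' Reads the simulated stack, aligns it and writes the aligned stack plus
#' the per-slice transform log.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the transform data frame.
#' @export
cmd_align <- function(cfg) {
  stack <- load_run_stack(cfg, prefer_aligned = FALSE)
  res <- align_rigid(stack)
  write_stack(res$stack, file.path(cfg$outdir, "stack_aligned"))
  write.csv(res$transforms, file.path(cfg$outdir, "alignment_transforms.csv"),
            row.names = FALSE)
  write_manifest(cfg, "align",
                 inputs = list(stack = "stack"),
                 outputs = list(stack_aligned = "stack_aligned",
                                transforms = "alignment_transforms.csv"),
                 counts = list(n_slices = length(stack)))
  invisible(res$transforms)
}

# operator emulation: on abortion, re-seed at the axon's true centre
truth_reseed_hook <- function(truth_slices, kept_slices, xy_scale) {
  function(event) {
    orig_slice <- kept_slices[event$slice]
    row <- truth_slices[truth_slices$axon_id == event$axon_id &
                          truth_slices$slice == orig_slice, ]
    if (!nrow(row)) return(NULL)
    c(round(row$row_um[1] / xy_scale + 0.5),
      round(row$col_um[1] / xy_scale + 0.5))
  }
}

#' Pipeline stage: segment every axon at each subsampling step
#'
#' Seeds every axon at its true slice-1 centre, propagates all traces at
#' every configured inter-slice subsampling step, resumes after each
#' abortion from the true centre (emulating the operator decision), and
#' writes per-step trace directories and abortion logs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list per step with the abortion data frame.
#' @export
cmd_segment <- function(cfg) {
  truth <- read.csv(require_file(file.path(cfg$outdir, "truth_slices.csv")))
  stack <- load_run_stack(cfg)
  xy <- cfg$phantom$xy_scale
  s1 <- truth[truth$slice == 1, ]
  seeds <- data.frame(axon_id = s1$axon_id,
                      row_px = round(s1$row_um / xy + 0.5),
                      col_px = round(s1$col_um / xy + 0.5))
  out <- list()
  for (step in cfg$subsample_steps) {
    sub <- subsample_stack(stack, step)
    kept <- attr(sub, "kept_slices")
    hook <- truth_reseed_hook(truth, kept, xy)
    res <- segment_stack(sub, seeds, cfg$segmentation, on_abort = hook)
    tdir <- file.path(cfg$outdir, sprintf("traces_step%d", step))
    write_traces(res$traces, res$abortions, tdir)
    out[[as.character(step)]] <- list(abortions = res$abortions,
                                      n_slices = length(sub))
  }
  write_manifest(cfg, "segment",
                 inputs = list(stack = "stack", truth = "truth_slices.csv"),
                 outputs = list(traces = sprintf("traces_step%d",
                                                 cfg$subsample_steps)),
                 counts = list(abortions = vapply(out, function(x)
                   nrow(x$abortions), integer(1))))
  invisible(out)
}

#' Pipeline stage: morphometry and segmentation QC
#'
#' Computes per-axon morphometry from the full-resolution traces, the
#' normalized area-fluctuation class comparison, abortion rates per
#' inter-slice interval, the abortion-versus-size decay fit and rank
#' correlation, and the axon-position analyses; writes a CSV morphometry
#' table, a JSON stats report and diagnostic figures.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the stats report list.
#' @export
cmd_qc <- function(cfg) {
  step1 <- cfg$subsample_steps[1]
  tdir <- require_file(file.path(cfg$outdir, sprintf("traces_step%d", step1)))
  traces <- read_traces(tdir)
  rates <- list(); ab_by_step <- list()
  for (step in cfg$subsample_steps) {
    d <- require_file(file.path(cfg$outdir, sprintf("traces_step%d", step),
                                "abortions.csv"))
    ab <- read.csv(d)
    n_sl <- length(seq(1, cfg$phantom$n_slices, by = step))
    rates[[as.character(step)]] <- abortion_rate(nrow(ab),
                                                 cfg$phantom$n_axons, n_sl)
    ab_by_step[[as.character(step)]] <- ab
  }
  rec <- axon_records(traces, ab_by_step[[as.character(step1)]])
  dev <- normalize_fluctuation(rec$per_slice)
  grp <- group_equal_n(rec$axons, cfg$k_classes)
  ct <- class_tests(grp, dev)
  se <- tryCatch(size_effect(rec$axons$abortion_count,
                             rec$axons$idealized_diameter_um),
                 error = function(e) list(error = conditionMessage(e)))
  pe <- position_effect(rec$axons)
  write.csv(rec$axons, file.path(cfg$outdir, "morphometry.csv"),
            row.names = FALSE)
  report <- list(abortion_rates = rates,
                 kruskal = ct$kruskal,
                 welch_p = as.data.frame(ct$welch_p),
                 classes = grp$classes,
                 size_effect = se,
                 position_effect = pe)
  jsonlite::write_json(report, file.path(cfg$outdir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  qc_figures(cfg, rec, dev, grp)
  write_manifest(cfg, "qc",
                 inputs = list(traces = basename(tdir)),
                 outputs = list(morphometry = "morphometry.csv",
                                report = "qc_report.json"),
                 counts = list(n_axons = nrow(rec$axons)))
  invisible(report)
}

qc_figures <- function(cfg, rec, dev, grp) {
  m <- merge(dev, grp$membership, by = "axon_id")
  grDevices::png(file.path(cfg$outdir, "fig_class_fluctuation.png"),
                 width = 700, height = 500)
  graphics::boxplot(deviation_pct ~ class, data = m,
                    xlab = "diameter class", ylab = "area deviation (%)",
                    main = "Normalized area fluctuation by size class")
  grDevices::dev.off()
  grDevices::png(file.path(cfg$outdir, "fig_size_vs_abortions.png"),
                 width = 700, height = 500)
  graphics::plot(rec$axons$idealized_diameter_um, rec$axons$abortion_count,
                 xlab = "idealized diameter (um)", ylab = "abortions",
                 main = "Tracing abortions vs axon size")
  grDevices::dev.off()
  grDevices::png(file.path(cfg$outdir, "fig_distance_vs_abortions.png"),
                 width = 700, height = 500)
  graphics::plot(rec$axons$dist_center_um, rec$axons$abortion_count,
                 xlab = "distance to nerve centre (um)", ylab = "abortions",
                 main = "Tracing abortions vs axon position")
  grDevices::dev.off()
  invisible(NULL)
}

#' Pipeline stage: mesh reconstruction
#'
#' Lofts the first `mesh_axons` complete traces into watertight meshes,
#' audits inter-axon overlaps before and after HC smoothing, decimates, and
#' exports the smoothed-decimated model as VRML 2.0 (named per axon) plus a
#' merged PLY, with a mesh-statistics table.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the mesh statistics data frame.
#' @export
cmd_mesh <- function(cfg) {
  step1 <- cfg$subsample_steps[1]
  tdir <- require_file(file.path(cfg$outdir, sprintf("traces_step%d", step1)))
  traces <- read_traces(tdir)
  ids <- head(sort(names(traces)), cfg$mesh_axons)
  z <- cfg$phantom$z_step
  meshes <- lapply(traces[ids], loft_trace, z_step = z)
  ov_raw <- overlap_errors(meshes)
  smoothed <- lapply(meshes, hc_laplacian_smooth,
                     iterations = cfg$smoothing_iterations)
  ov_sm <- overlap_errors(smoothed)
  decimated <- lapply(smoothed, quadric_decimate,
                      target_vertex_fraction = cfg$decimation_fraction)
  stats <- do.call(rbind, lapply(ids, function(id) {
    s0 <- mesh_stats(meshes[[id]])
    s2 <- mesh_stats(decimated[[id]])
    data.frame(axon_id = id, vertices = s0$vertex_count,
               faces = s0$face_count, volume_um3 = s0$volume,
               vertices_decimated = s2$vertex_count,
               volume_decimated_um3 = s2$volume, euler = s2$euler)
  }))
  export_mesh(decimated, file.path(cfg$outdir, "model.wrl"), "vrml")
  export_mesh(decimated, file.path(cfg$outdir, "model.ply"), "ply")
  write.csv(stats, file.path(cfg$outdir, "mesh_stats.csv"), row.names = FALSE)
  jsonlite::write_json(list(overlap_before_smoothing = ov_raw$total,
                            overlap_after_smoothing = ov_sm$total),
                       file.path(cfg$outdir, "overlap_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "mesh",
                 inputs = list(traces = basename(tdir)),
                 outputs = list(model = c("model.wrl", "model.ply"),
                                stats = "mesh_stats.csv"),
                 counts = list(n_meshes = length(ids)))
  invisible(stats)
}

#' Pipeline stage: summary report
#'
#' Collects the QC and mesh outputs of a run into one JSON summary
#' comparable across runs.
#'
#' @param cfg A [run_config()].
#' @return The summary list (also written to `report.json`).
#' @export
cmd_report <- function(cfg) {
  qc <- jsonlite::read_json(require_file(file.path(cfg$outdir,
                                                   "qc_report.json")))
  ov <- jsonlite::read_json(require_file(file.path(cfg$outdir,
                                                   "overlap_report.json")))
  ms <- read.csv(require_file(file.path(cfg$outdir, "mesh_stats.csv")))
  summary <- list(seed = cfg$seed,
                  abortion_rates = qc$abortion_rates,
                  kruskal_p = qc$kruskal$p.value,
                  size_effect = qc$size_effect,
                  position_effect = qc$position_effect,
                  overlap = ov,
                  mesh = list(n = nrow(ms),
                              total_vertices = sum(ms$vertices),
                              total_vertices_decimated =
                                sum(ms$vertices_decimated)))
  jsonlite::write_json(summary, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg, "report",
                 inputs = list("qc_report.json", "overlap_report.json",
                               "mesh_stats.csv"),
                 outputs = list(report = "report.json"))
  summary
}

#' Run the whole pipeline
#'
#' `simulate -> align -> segment -> qc -> mesh -> report` in order.
#'
#' @param cfg A [run_config()].
#' @return The report summary list.
#' @export
run_pipeline <- function(cfg) {
  cmd_simulate(cfg)
  cmd_align(cfg)
  cmd_segment(cfg)
  cmd_qc(cfg)
  cmd_mesh(cfg)
  cmd_report(cfg)
}
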