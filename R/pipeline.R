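# File handling and orchestration: CSV density tables, TIFF label/intensity
# images, JSON configs, and a staged end-to-end runner that writes a manifest
# with checksums so every output is reproducible from config + seed alone.

#' Read a cluster density--area table
#'
#' CSV with columns `area_um2` and `density_per_mm2`; rows are validated
#' (positive areas, non-negative finite densities) and errors name the
#' offending line.
#'
#' @param path CSV path.
#' @return data frame with columns `x` (area, um^2) and `y` (density per mm^2),
#'   ready for [fit_power_law()].
#' @export
read_density_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path)
  need <- c("area_um2", "density_per_mm2")
  if (!all(need %in% names(df)))
    stop(sprintf("density table must have columns %s", paste(need, collapse = ", ")))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (!is.finite(df$area_um2[i]) || df$area_um2[i] <= 0)
      stop(sprintf("line %d: area_um2 must be a positive number", line))
    if (!is.finite(df$density_per_mm2[i]) || df$density_per_mm2[i] < 0)
      stop(sprintf("line %d: density_per_mm2 must be non-negative", line))
  }
  data.frame(x = df$area_um2, y = df$density_per_mm2)
}

#' Write a density--area table
#'
#' @param points data frame with columns `x`, `y` (or `area_um2`,
#'   `density_per_mm2`).
#' @param path output CSV path.
#' @export
write_density_table <- function(points, path) {
  if (all(c("x", "y") %in% names(points)))
    points <- data.frame(area_um2 = points$x, density_per_mm2 = points$y)
  write.csv(points[, c("area_um2", "density_per_mm2")], path, row.names = FALSE)
  invisible(path)
}

#' Write/read a binned size distribution
#'
#' CSV with columns `bin_lo_um2`, `bin_hi_um2`, `density_per_mm2`; the
#' round trip reproduces the distribution to float precision.
#'
#' @param dist a [size_distribution()].
#' @param path CSV path.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  df <- data.frame(bin_lo_um2 = head(dist$bin_edges, -1L),
                   bin_hi_um2 = tail(dist$bin_edges, -1L),
                   density_per_mm2 = dist$density)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  df <- read.csv(path)
  need <- c("bin_lo_um2", "bin_hi_um2", "density_per_mm2")
  if (!all(need %in% names(df)))
    stop(sprintf("distribution table must have columns %s",
                 paste(need, collapse = ", ")))
  size_distribution(c(df$bin_lo_um2, df$bin_hi_um2[nrow(df)]),
                    df$density_per_mm2)
}

#' TIFF input/output for label and intensity images
#'
#' Label images are stored as 16-bit TIFF (labels up to 65535; lossless round
#' trip); intensity images are stored as 32-bit float TIFF after division by
#' `scale` (the tiff format stores floats in `[0, 1]`), with the scale
#' restored on read. Multi-page images (3D stacks, time series) are supported
#' via lists of slices.
#'
#' @param img a [label_image()], matrix, or list of matrices (multi-page).
#' @param path TIFF path.
#' @param spacing per-axis pixel size recorded on read, micrometres.
#' @param scale intensity scale factor for float storage.
#' @name tiff_io
NULL

#' @rdname tiff_io
#' @export
write_label_tiff <- function(img, path) {
  x <- if (inherits(img, "label_image")) img$data else img
  pages <- if (is.list(x)) x else if (length(dim(x)) == 3L)
    lapply(seq_len(dim(x)[3]), function(k) x[, , k]) else list(x)
  if (any(vapply(pages, max, numeric(1)) > 65535))
    stop("labels above 65535 cannot be stored as 16-bit TIFF")
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_label_tiff <- function(path, spacing = c(1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  x <- if (length(pages) == 1L) pages[[1L]] else
    array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  label_image(x, if (length(dim(x)) == 3L && length(spacing) == 2L)
    c(spacing, 1) else spacing)
}

#' @rdname tiff_io
#' @export
write_intensity_tiff <- function(img, path, scale = 65535) {
  pages <- if (is.list(img)) img else list(img)
  if (any(vapply(pages, max, numeric(1)) > scale))
    stop("intensity exceeds `scale`; increase it")
  if (any(vapply(pages, min, numeric(1)) < 0))
    stop("negative intensities cannot be stored; offset the image first")
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_intensity_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) p * scale)
  if (length(pages) == 1L) pages[[1L]] else pages
}

pipeline_stages <- c("mosaic", "cells", "render", "timeseries",
                     "fit_powerlaw", "calibrate", "morpho")

#' Run an end-to-end pipeline from a JSON config
#'
#' Executes the requested stages in dependency order -- synthetic mosaic,
#' cell packing, channel rendering, competition time series, power-law fit,
#' rate calibration, morphometry -- writing each stage's outputs under
#' `out_dir` and finally a manifest (JSON) echoing the config and recording
#' per-file MD5 checksums, seeds and wall-clock times. All randomness derives
#' from the single global seed, so identical config + seed reproduce
#' byte-identical outputs.
#'
#' @param config path to a JSON config file, or an equivalent list. Top-level
#'   fields: `stages` (subset of mosaic, cells, render, timeseries,
#'   fit_powerlaw, calibrate, morpho), `seed`, `out_dir`, and optional
#'   per-stage parameter blocks (`mosaic`, `cells`, `render`, `timeseries`,
#'   `calibrate`).
#' @param out_dir output directory (overrides the config field if given).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
  else config
  known_top <- c("stages", "seed", "out_dir", pipeline_stages)
  bad <- setdiff(names(cfg), known_top)
  if (length(bad))
    stop(sprintf("config error: unknown field(s) %s", paste(bad, collapse = ", ")))
  stages <- unlist(cfg$stages)
  if (is.null(stages) || length(stages) == 0L) stop("config error: no `stages` given")
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    stop(sprintf("config error: unknown stage name(s) %s; valid stages are %s",
                 paste(bad, collapse = ", "), paste(pipeline_stages, collapse = ", ")))
  stages <- pipeline_stages[pipeline_stages %in% stages]  # dependency order
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out_dir <- if (!is.null(out_dir)) out_dir else
    if (!is.null(cfg$out_dir)) cfg$out_dir else stop("config error: no `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  arg <- function(stage, name, default) {
    v <- cfg[[stage]][[name]]
    if (is.null(v)) default else v
  }
  state <- list()
  stage_log <- list()
  files <- character(0)
  emit <- function(f) files <<- c(files, f)

  for (st in stages) {
    t0 <- Sys.time()
    stage_seed <- seed + match(st, pipeline_stages)  # documented derivation
    switch(st,
      mosaic = {
        mo <- generate_mosaic(
          tissue_shape = unlist(arg("mosaic", "tissue_shape", c(512, 512))),
          pixel_size = arg("mosaic", "pixel_size", 1),
          powerlaw = c(a = arg("mosaic", "a", 2436), b = arg("mosaic", "b", -1.067)),
          target_label_fraction = arg("mosaic", "target_label_fraction", 20),
          seed = stage_seed)
        state$mosaic <- mo
        write_label_tiff(mo$mask, file.path(out_dir, "mosaic_mask.tif"))
        write.csv(mo$truth$clusters, file.path(out_dir, "mosaic_clusters.csv"),
                  row.names = FALSE)
        emit(file.path(out_dir, c("mosaic_mask.tif", "mosaic_clusters.csv")))
      },
      cells = {
        if (is.null(state$mosaic)) stop("stage `cells` needs stage `mosaic`")
        pk <- generate_cell_packing(
          state$mosaic,
          mean_cell_diameter = arg("cells", "mean_cell_diameter", 8),
          compaction = arg("cells", "compaction", 1),
          nucleus_jitter = arg("cells", "nucleus_jitter", 0.5),
          seed = stage_seed)
        state$packing <- pk
        write_label_tiff(pk$cells, file.path(out_dir, "cell_labels.tif"))
        write.csv(pk$nuclei, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
        emit(file.path(out_dir, c("cell_labels.tif", "nuclei.csv")))
      },
      render = {
        if (is.null(state$packing)) stop("stage `render` needs stage `cells`")
        ch <- render_channels(
          state$packing,
          base_intensity = arg("render", "base_intensity", 100),
          clone_normal_factor = arg("render", "clone_normal_factor", 0.5),
          gaussian_noise_sd = arg("render", "gaussian_noise_sd", 2),
          seed = stage_seed)
        state$channels <- ch
        write_intensity_tiff(pmax(ch$membrane, 0),
                             file.path(out_dir, "membrane.tif"))
        emit(file.path(out_dir, "membrane.tif"))
      },
      timeseries = {
        if (is.null(state$mosaic)) stop("stage `timeseries` needs stage `mosaic`")
        ts <- generate_time_series(
          state$mosaic, d_true = arg("timeseries", "d", 0.1),
          snapshot_days = unlist(arg("timeseries", "snapshot_days", c(0, 7, 35))),
          n_replicates = arg("timeseries", "n_replicates", 1),
          seed = stage_seed)
        state$timeseries <- ts
        for (day in ts$days)
          write_distribution(time_series_distribution(ts, day),
                             file.path(out_dir, sprintf("density_day%g.csv", day)))
        emit(file.path(out_dir, sprintf("density_day%g.csv", ts$days)))
      },
      fit_powerlaw = {
        if (is.null(state$mosaic)) stop("stage `fit_powerlaw` needs stage `mosaic`")
        cl <- state$mosaic$truth$clusters
        edges <- exp(seq(log(25), log(20000), length.out = 13))
        mids <- sqrt(edges[-1] * edges[-length(edges)])
        counts <- table(cut(cl$area_um2, edges, include.lowest = TRUE))
        pts <- data.frame(x = mids,
                          y = as.integer(counts) /
                            (diff(edges) * state$mosaic$truth$tissue_area_mm2))
        pts <- pts[pts$y > 0, ]
        pl <- fit_power_law(pts)
        state$powerlaw <- pl
        jsonlite::write_json(list(a = pl$a, b = pl$b, a_ci = pl$a_ci,
                                  b_ci = pl$b_ci, rss = pl$rss),
                             file.path(out_dir, "powerlaw_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        emit(file.path(out_dir, "powerlaw_fit.json"))
      },
      calibrate = {
        if (is.null(state$timeseries)) stop("stage `calibrate` needs stage `timeseries`")
        ts <- state$timeseries
        target_day <- arg("calibrate", "target_day", max(ts$days))
        target <- time_series_distribution(ts, target_day)
        ens <- patch_ensemble_from_records(state$mosaic$truth$clusters,
                                           ts$tissue_area_mm2,
                                           delta = state$mosaic$mask$spacing[1])
        cal <- calibrate_d(ens, target, t_final = target_day,
                           n_replicates = arg("calibrate", "n_replicates", 5),
                           seed = stage_seed,
                           d_bounds = unlist(arg("calibrate", "d_bounds", c(0, 0.4))),
                           n_grid = arg("calibrate", "n_grid", 6))
        state$calibration <- cal
        jsonlite::write_json(list(d_hat = cal$d_hat, objective = cal$objective,
                                  trace = cal$trace),
                             file.path(out_dir, "calibration.json"),
                             auto_unbox = TRUE, digits = NA)
        emit(file.path(out_dir, "calibration.json"))
      },
      morpho = {
        if (is.null(state$mosaic)) stop("stage `morpho` needs stage `mosaic`")
        recs <- segment_clusters(label_image(
          (state$mosaic$mask$data > 0) * 1L, state$mosaic$mask$spacing))
        dist <- density_by_size(recs, state$mosaic$truth$tissue_area_mm2)
        write.csv(recs, file.path(out_dir, "cluster_records.csv"),
                  row.names = FALSE)
        write_distribution(dist, file.path(out_dir, "cluster_density.csv"))
        emit(file.path(out_dir, c("cluster_records.csv", "cluster_density.csv")))
      })
    stage_log[[st]] <- list(seed = stage_seed,
                            wall_clock_s = as.numeric(difftime(Sys.time(), t0,
                                                               units = "secs")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("clonecomp")),
    config = cfg, global_seed = seed, stages = stage_log,
    checksums = as.list(setNames(tools::md5sum(files), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
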