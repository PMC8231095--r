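# Synthetic mosaic-tissue generator. Every dataset the pipeline consumes can
# be generated here with exported ground truth: mosaic cluster masks whose
# sizes follow the density-area power law, Voronoi cell packings with nuclei
# and tunable within-clone compaction, pseudo-fluorescence channels with
# attenuated clone-normal interfaces, and competition-model time series at a
# known rate d.

#' Sample cluster areas from a truncated power-law density
#'
#' Inverse-CDF sampling from the density proportional to `x^b` on
#' `[range[1], range[2]]` (um^2), the size law of early-time clone clusters.
#'
#' @param n number of areas to draw.
#' @param powerlaw named vector/list with `a` and `b` (only `b` shapes the
#'   distribution; `a` scales expected counts).
#' @param range lower/upper truncation, um^2.
#' @return numeric vector of areas.
#' @export
sample_cluster_areas <- function(n, powerlaw = c(a = 2436, b = -1.067),
                                 range = c(25, 20000)) {
  b <- as.numeric(powerlaw[["b"]])
  u <- runif(n)
  if (abs(b + 1) < 1e-12) {
    exp(log(range[1]) + u * (log(range[2]) - log(range[1])))
  } else {
    b1 <- b + 1
    (range[1]^b1 + u * (range[2]^b1 - range[1]^b1))^(1 / b1)
  }
}

#' Truncated power-law cumulative distribution of cluster areas
#'
#' @param x areas, um^2.
#' @param powerlaw named vector/list with `b`.
#' @param range truncation bounds, um^2.
#' @return CDF values (for comparing realised area samples to the target law).
#' @export
power_law_cdf <- function(x, powerlaw = c(a = 2436, b = -1.067),
                          range = c(25, 20000)) {
  b <- as.numeric(powerlaw[["b"]])
  x <- pmin(pmax(x, range[1]), range[2])
  if (abs(b + 1) < 1e-12) {
    (log(x) - log(range[1])) / (log(range[2]) - log(range[1]))
  } else {
    b1 <- b + 1
    (x^b1 - range[1]^b1) / (range[2]^b1 - range[1]^b1)
  }
}

#' Generate a mosaic tissue of power-law-sized clone clusters
#'
#' Disc-shaped clusters with areas drawn from the truncated power law are
#' placed uniformly at random without overlap (and with a minimum gap so
#' clusters stay discrete under segmentation) until the target labelled-area
#' fraction is reached to within one percentage point.
#'
#' @param tissue_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size pixel side, micrometres.
#' @param powerlaw named vector with `a`, `b` of the density--area law.
#' @param target_label_fraction percent of tissue area to label, in (0, 100).
#' @param area_range cluster-area truncation bounds, um^2.
#' @param min_gap_px minimum gap between clusters, pixels.
#' @param seed RNG seed.
#' @param max_attempts placement attempts before giving up.
#' @return object of class `mosaic_tissue`: `mask` (a [label_image()] of
#'   cluster ids) and `truth` (cluster table with id/area/centroid, realised
#'   label fraction, the generating power law, seed and spec echo).
#' @export
generate_mosaic <- function(tissue_shape = c(1024, 1024), pixel_size = 1,
                            powerlaw = c(a = 2436, b = -1.067),
                            target_label_fraction = 20,
                            area_range = c(25, 20000), min_gap_px = 2L,
                            seed = 1L, max_attempts = 1e5) {
  if (any(tissue_shape < 1)) stop("tissue must have positive area")
  if (target_label_fraction <= 0 || target_label_fraction >= 100)
    stop("`target_label_fraction` must be in (0, 100)")
  set.seed(seed)
  nr <- tissue_shape[1]; nc <- tissue_shape[2]
  npx_tissue <- nr * nc
  labels <- matrix(0L, nr, nc)
  blocked <- matrix(FALSE, nr, nc)
  gap <- expand.grid(dr = -min_gap_px:min_gap_px, dc = -min_gap_px:min_gap_px)
  clusters <- list()
  labelled <- 0L
  attempts <- 0L
  id <- 0L
  repeat {
    frac <- 100 * labelled / npx_tissue
    if (frac >= target_label_fraction - 0.25) break
    area <- sample_cluster_areas(1L, powerlaw, area_range)
    npx <- max(1L, round(area / pixel_size^2))
    if (100 * (labelled + npx) / npx_tissue > target_label_fraction + 1) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("could not reach target fraction in %d attempts (achieved %.2f%%)",
                     as.integer(max_attempts), frac))
      next
    }
    off <- disc_offsets(npx)
    placed <- FALSE
    for (try in 1:50) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("could not reach target fraction in %d attempts (achieved %.2f%%)",
                     as.integer(max_attempts), frac))
      ci <- sample.int(nr, 1L); cj <- sample.int(nc, 1L)
      rr <- off[, 1L] + ci; cc <- off[, 2L] + cj
      if (min(rr) < 1L || max(rr) > nr || min(cc) < 1L || max(cc) > nc) next
      px <- cbind(rr, cc)
      if (any(blocked[px])) next
      id <- id + 1L
      labels[px] <- id
      for (g in seq_len(nrow(gap))) {
        gr <- pmin(pmax(rr + gap$dr[g], 1L), nr)
        gc <- pmin(pmax(cc + gap$dc[g], 1L), nc)
        blocked[cbind(gr, gc)] <- TRUE
      }
      labelled <- labelled + npx
      clusters[[id]] <- data.frame(
        id = id, n_pixels = npx, area_um2 = npx * pixel_size^2,
        centroid_row_um = (mean(rr) - 1) * pixel_size,
        centroid_col_um = (mean(cc) - 1) * pixel_size)
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  truth <- list(
    clusters = if (length(clusters)) do.call(rbind, clusters) else
      data.frame(id = integer(), n_pixels = integer(), area_um2 = numeric(),
                 centroid_row_um = numeric(), centroid_col_um = numeric()),
    label_fraction = 100 * labelled / npx_tissue,
    powerlaw = powerlaw, area_range = area_range, seed = seed,
    tissue_area_mm2 = npx_tissue * pixel_size^2 / 1e6,
    spec = list(tissue_shape = tissue_shape, pixel_size = pixel_size,
                target_label_fraction = target_label_fraction,
                min_gap_px = min_gap_px))
  structure(list(mask = label_image(labels, rep(pixel_size, 2L)), truth = truth),
            class = "mosaic_tissue")
}

#' @export
print.mosaic_tissue <- function(x, ...) {
  cat(sprintf("<mosaic_tissue> %s px, %d clusters, %.2f%% labelled\n",
              paste(dim(x$mask$data), collapse = " x "),
              nrow(x$truth$clusters), x$truth$label_fraction))
  invisible(x)
}

# lattice seed points with spacing `s` px, random phase, jittered
jittered_lattice <- function(nr, nc, s, jitter_sd) {
  phase <- runif(2, 0, s)
  g <- expand.grid(row = seq(phase[1], nr + s, by = s),
                   col = seq(phase[2], nc + s, by = s))
  g$row <- g$row + rnorm(nrow(g), 0, jitter_sd)
  g$col <- g$col + rnorm(nrow(g), 0, jitter_sd)
  g
}

#' Pack cells into a mosaic tissue by region-restricted Voronoi tessellation
#'
#' Seed points on a jittered square lattice are placed at spacing equal to the
#' mean cell diameter outside clones and at `compaction` times that spacing
#' inside clones; every pixel is then assigned to the nearest seed of its own
#' region (clone cluster or normal tissue), so cells partition the tissue and
#' never cross a cluster boundary. Each cell carries one nucleus centroid near
#' its seed. Within-clone internuclear spacing therefore scales with the
#' compaction factor, emulating the tighter packing of mutant clusters.
#'
#' @param mosaic a [generate_mosaic()] result (or a `label_image` cluster mask).
#' @param mean_cell_diameter mean cell diameter, micrometres.
#' @param compaction factor in (0, 1] scaling seed spacing inside clones.
#' @param nucleus_jitter SD of the nucleus offset from the cell seed, um.
#' @param seed RNG seed.
#' @return object of class `cell_packing`: `cells` (a [label_image()] of cell
#'   ids partitioning the image), `nuclei` (data frame: `label`, `row_um`,
#'   `col_um`, `clone`, `cluster_id`), and `truth` (per-cell table and the
#'   spec echo).
#' @export
generate_cell_packing <- function(mosaic, mean_cell_diameter = 8,
                                  compaction = 1, nucleus_jitter = 0.5,
                                  seed = 1L) {
  mask <- if (inherits(mosaic, "mosaic_tissue")) mosaic$mask else
    as_label_image(mosaic)
  if (abs(mask$spacing[1] - mask$spacing[2]) > 1e-12)
    stop("cell packing requires isotropic pixels")
  ps <- mask$spacing[1]
  s <- mean_cell_diameter / ps
  if (s < 2) stop("mean cell diameter must be at least 2 pixels")
  if (compaction <= 0 || compaction > 1) stop("`compaction` must be in (0, 1]")
  set.seed(seed)
  x <- mask$data
  nr <- nrow(x); nc <- ncol(x)
  cluster_ids <- setdiff(sort(unique(as.vector(x))), 0L)

  seeds <- list()
  # normal-tissue seeds
  g <- jittered_lattice(nr, nc, s, 0.15 * s)
  g$row <- pmin(pmax(round(g$row), 1L), nr)
  g$col <- pmin(pmax(round(g$col), 1L), nc)
  g <- g[x[cbind(g$row, g$col)] == 0L, , drop = FALSE]
  g <- g[!duplicated(g[, c("row", "col")]), , drop = FALSE]
  g$cluster_id <- 0L
  seeds[["normal"]] <- g
  # clone seeds, one compacted lattice per cluster
  for (cid in cluster_ids) {
    px <- which(x == cid, arr.ind = TRUE)
    sc <- compaction * s
    gg <- jittered_lattice(nr, nc, sc, 0.15 * sc)
    gg$row <- pmin(pmax(round(gg$row), 1L), nr)
    gg$col <- pmin(pmax(round(gg$col), 1L), nc)
    inb <- gg$row >= min(px[, 1]) & gg$row <= max(px[, 1]) &
      gg$col >= min(px[, 2]) & gg$col <= max(px[, 2])
    gg <- gg[inb, , drop = FALSE]
    gg <- gg[x[cbind(gg$row, gg$col)] == cid, , drop = FALSE]
    gg <- gg[!duplicated(gg[, c("row", "col")]), , drop = FALSE]
    if (nrow(gg) == 0L)
      gg <- data.frame(row = px[which.min(rowSums(sweep(px, 2, colMeans(px))^2)), 1],
                       col = px[which.min(rowSums(sweep(px, 2, colMeans(px))^2)), 2])
    gg$cluster_id <- cid
    seeds[[paste0("c", cid)]] <- gg
  }
  seeds <- do.call(rbind, seeds)
  seeds$label <- seq_len(nrow(seeds))

  cells <- matrix(0L, nr, nc)
  for (cid in c(0L, cluster_ids)) {
    sset <- seeds[seeds$cluster_id == cid, , drop = FALSE]
    pix <- which(x == cid, arr.ind = TRUE)
    if (nrow(pix) == 0L) next
    if (nrow(sset) == 1L) {
      cells[pix] <- sset$label
    } else {
      nn <- class::knn1(as.matrix(sset[, c("row", "col")]), pix,
                        factor(sset$label))
      cells[pix] <- as.integer(as.character(nn))
    }
  }
  # seeds whose region pixels were all captured by other seeds leave no cell
  kept <- sort(unique(as.vector(cells)))
  kept <- kept[kept > 0L]
  seeds <- seeds[seeds$label %in% kept, , drop = FALSE]

  nuclei <- data.frame(
    label = seeds$label,
    row_um = (seeds$row - 1) * ps + rnorm(nrow(seeds), 0, nucleus_jitter),
    col_um = (seeds$col - 1) * ps + rnorm(nrow(seeds), 0, nucleus_jitter),
    clone = seeds$cluster_id > 0L,
    cluster_id = seeds$cluster_id)
  npx_cell <- table(factor(as.vector(cells[cells > 0L]), levels = nuclei$label))
  truth <- list(
    cells = data.frame(nuclei,
                       n_pixels = as.integer(npx_cell),
                       area_um2 = as.integer(npx_cell) * ps^2),
    mean_cell_diameter = mean_cell_diameter, compaction = compaction,
    nucleus_jitter = nucleus_jitter, seed = seed)
  structure(list(cells = label_image(cells, mask$spacing),
                 nuclei = nuclei, cluster_mask = mask, truth = truth),
            class = "cell_packing")
}

#' @export
print.cell_packing <- function(x, ...) {
  cat(sprintf("<cell_packing> %d cells (%d clone), compaction %.2f\n",
              nrow(x$nuclei), sum(x$nuclei$clone), x$truth$compaction))
  invisible(x)
}

#' Render pseudo-fluorescence channels from a cell packing
#'
#' Produces three channels aligned with the cell label image: a membrane
#' channel with `base_intensity` on every cell--cell interface pixel,
#' attenuated by `clone_normal_factor` on clone-normal interfaces (emulating
#' reduced junctional E-cadherin at mutant-normal contacts); a clone channel
#' filling clone-cell pixels; and a nuclei channel with small discs at nucleus
#' centres. Optional Poisson shot noise (intensity-dependent) and Gaussian
#' read noise are applied, seeded and reproducible.
#'
#' @param packing a [generate_cell_packing()] result.
#' @param base_intensity interface/fill intensity in arbitrary units.
#' @param clone_normal_factor attenuation factor f in `[0, 2]` applied to
#'   clone-normal interface pixels.
#' @param gaussian_noise_sd SD of additive Gaussian noise (0 = off).
#' @param poisson_scaling photons per intensity unit for shot noise (0 = off).
#' @param seed RNG seed.
#' @return list with matrices `membrane`, `clone`, `nuclei`, the `cell_graph`
#'   used, and the spec echo (`truth`).
#' @export
render_channels <- function(packing, base_intensity = 100,
                            clone_normal_factor = 1, gaussian_noise_sd = 0,
                            poisson_scaling = 0, seed = 1L) {
  stopifnot(inherits(packing, "cell_packing"))
  if (clone_normal_factor < 0 || clone_normal_factor > 2)
    stop("`clone_normal_factor` must lie in [0, 2]")
  if (gaussian_noise_sd < 0 || poisson_scaling < 0)
    stop("noise parameters must be >= 0")
  set.seed(seed)
  graph <- build_cell_graph(packing$cells, packing$nuclei)
  dims <- dim(packing$cells$data)
  membrane <- matrix(0, dims[1], dims[2])
  membrane[graph$pixel_class > 0L] <- base_intensity
  membrane[graph$pixel_class == 3L] <- base_intensity * clone_normal_factor
  clone <- matrix(0, dims[1], dims[2])
  clone_cells <- packing$nuclei$label[packing$nuclei$clone]
  clone[packing$cells$data %in% clone_cells] <- base_intensity
  nuclei <- matrix(0, dims[1], dims[2])
  ps <- packing$cells$spacing[1]
  nr <- round(packing$nuclei$row_um / ps) + 1
  ncl <- round(packing$nuclei$col_um / ps) + 1
  for (o in list(c(0, 0), c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    rr <- pmin(pmax(nr + o[1], 1), dims[1])
    cc <- pmin(pmax(ncl + o[2], 1), dims[2])
    nuclei[cbind(rr, cc)] <- base_intensity
  }
  add_noise <- function(img) {
    if (poisson_scaling > 0)
      img <- matrix(rpois(length(img), as.vector(img) * poisson_scaling),
                    nrow(img)) / poisson_scaling
    if (gaussian_noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, gaussian_noise_sd), nrow(img))
    img
  }
  list(membrane = add_noise(membrane), clone = add_noise(clone),
       nuclei = add_noise(nuclei), graph = graph,
       truth = list(base_intensity = base_intensity,
                    clone_normal_factor = clone_normal_factor,
                    gaussian_noise_sd = gaussian_noise_sd,
                    poisson_scaling = poisson_scaling, seed = seed))
}

#' Simulate shrinkage time series of a mosaic tissue
#'
#' Runs the lattice competition model independently on every cluster of a
#' mosaic (each cluster embedded in a wild-type frame) and emits day-stamped
#' cluster areas and density-by-size tables, with the generating rate recorded
#' as ground truth. Clusters only shrink, so simulating them separately is
#' exact.
#'
#' @param mosaic a [generate_mosaic()] result.
#' @param d_true competition rate, per day (>= 0).
#' @param snapshot_days ascending days at which to record (must include 0 to
#'   echo the initial state).
#' @param n_replicates independent whole-tissue replicates.
#' @param seed base seed; per-(replicate, cluster) seeds are derived from it.
#' @param bins size-distribution bin edges, um^2.
#' @param store_masks keep per-day cluster label masks? (memory-heavy)
#' @return object of class `competition_time_series`: `days`, `areas` (array
#'   clusters x days x replicates, um^2), `tables` (list per replicate of
#'   [size_distribution()]s per day), `masks` (optional), `tissue_area_mm2`,
#'   `truth` (d_true, seed, per-cluster fates).
#' @export
generate_time_series <- function(mosaic, d_true, snapshot_days = c(0, 7, 35),
                                 n_replicates = 1L, seed = 1L,
                                 bins = default_bin_edges(),
                                 store_masks = FALSE) {
  stopifnot(inherits(mosaic, "mosaic_tissue"))
  if (d_true < 0) stop("`d_true` must be >= 0")
  snapshot_days <- sort(unique(as.numeric(snapshot_days)))
  ps <- mosaic$mask$spacing[1]
  cl <- mosaic$truth$clusters
  ncl <- nrow(cl)
  x <- mosaic$mask$data
  t_final <- max(snapshot_days)
  areas <- array(NA_real_, c(ncl, length(snapshot_days), n_replicates),
                 dimnames = list(NULL, paste0("day", snapshot_days), NULL))
  masks <- if (store_masks)
    vector("list", n_replicates) else NULL
  tables <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    day_masks <- if (store_masks)
      lapply(snapshot_days, function(d) matrix(0L, nrow(x), ncol(x))) else NULL
    for (ci in seq_len(ncl)) {
      px <- which(x == cl$id[ci], arr.ind = TRUE)
      rb <- range(px[, 1]); cb <- range(px[, 2])
      occ <- (x[rb[1]:rb[2], cb[1]:cb[2], drop = FALSE] == cl$id[ci]) * 1L
      g0 <- grid_state(occ, delta = ps, boundary = "wildtype_frame")
      pars <- simulation_params(
        d = d_true, t_final = max(t_final, 1e-9),
        seed = as.integer((seed + (r - 1L) * ncl + (ci - 1L)) %% .Machine$integer.max),
        snapshot_times = snapshot_days)
      traj <- simulate_competition(g0, pars)
      areas[ci, , r] <- traj$observables$mutant_count * ps^2
      if (store_masks) {
        for (k in seq_along(snapshot_days)) {
          occ_k <- traj$snapshots[[k]]$occupancy
          sub <- day_masks[[k]][rb[1]:rb[2], cb[1]:cb[2], drop = FALSE]
          sub[occ_k == 1L] <- cl$id[ci]
          day_masks[[k]][rb[1]:rb[2], cb[1]:cb[2]] <- sub
        }
      }
    }
    tables[[r]] <- lapply(seq_along(snapshot_days), function(k) {
      rec <- data.frame(area_um2 = areas[, k, r])
      rec <- rec[rec$area_um2 > 0, , drop = FALSE]
      density_by_size(rec, mosaic$truth$tissue_area_mm2, bins)
    })
    names(tables[[r]]) <- paste0("day", snapshot_days)
    if (store_masks)
      masks[[r]] <- lapply(day_masks, label_image,
                           spacing = mosaic$mask$spacing)
  }
  structure(list(days = snapshot_days, areas = areas, tables = tables,
                 masks = masks, tissue_area_mm2 = mosaic$truth$tissue_area_mm2,
                 bins = bins,
                 truth = list(d_true = d_true, seed = seed,
                              extinct_fraction = mean(areas[, length(snapshot_days), ] == 0))),
            class = "competition_time_series")
}

#' Average density-by-size table of a time series at one day
#'
#' @param ts a [generate_time_series()] result.
#' @param day one of the snapshot days.
#' @return a [size_distribution()] averaged over replicates.
#' @export
time_series_distribution <- function(ts, day) {
  k <- match(day, ts$days)
  if (is.na(k)) stop("`day` is not one of the recorded snapshot days")
  dens <- rowMeans(vapply(ts$tables, function(tb) tb[[k]]$density,
                          numeric(length(ts$bins) - 1L)))
  size_distribution(ts$bins, dens, tissue_area_mm2 = ts$tissue_area_mm2)
}

#' Build a patch ensemble from observed cluster records
#'
#' One disc patch per observed cluster, each carrying weight
#' `1 / tissue_area_mm2` (its contribution to cluster density), so predicted
#' distributions are directly comparable to density-by-size tables measured on
#' the same tissue. This is the data-anchored alternative to
#' [seed_patch_ensemble()], which seeds from a fitted power law.
#'
#' @param records data frame with an `area_um2` column (e.g. the cluster table
#'   of a mosaic, or [segment_clusters()] output).
#' @param tissue_area_mm2 tissue area the records came from.
#' @param delta lattice spacing, micrometres.
#' @return a `patch_ensemble`.
#' @export
patch_ensemble_from_records <- function(records, tissue_area_mm2, delta = 1) {
  stopifnot(tissue_area_mm2 > 0)
  ens <- lapply(records$area_um2, function(x) {
    g <- disc_patch_grid(x, delta = delta)
    list(area_um2 = sum(g$occupancy) * delta^2, weight = 1 / tissue_area_mm2,
         grid = g)
  })
  structure(ens, class = "patch_ensemble")
}
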