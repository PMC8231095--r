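# Calibration of the competition rate d against cluster-size distributions.
#
# The workflow mirrors the model-data comparison: fit the density-area power
# law to early-time data, seed an ensemble of disc patches with densities given
# by the law, simulate the ensemble forward, and pick the d whose predicted
# late-time density-by-size curve best fits the observed one in the
# least-squares sense. Common random numbers make the stochastic objective a
# deterministic function of d, so a scalar bounded minimiser applies.

#' Default cluster-size bin edges (um^2)
#'
#' Anchored at the 2,000 um^2 threshold used when comparing small-cluster
#' densities between time points; the last bin is open-ended.
#' @export
default_bin_edges <- function() c(0, 500, 1000, 2000, 5000, 10000, 20000, Inf)

#' Binned cluster density by size
#'
#' @param bin_edges ascending numeric vector of area bin edges, um^2.
#' @param density clusters per mm^2 tissue in each bin
#'   (`length(bin_edges) - 1` values).
#' @param tissue_area_mm2 tissue area the densities are normalised to
#'   (NA when the distribution is a model prediction).
#' @param extinction_fraction fraction of (density-weighted) patches that went
#'   extinct, for model predictions.
#' @return object of class `size_distribution`.
#' @export
size_distribution <- function(bin_edges, density, tissue_area_mm2 = NA_real_,
                              extinction_fraction = NA_real_) {
  bin_edges <- as.numeric(bin_edges)
  density <- as.numeric(density)
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must be ascending")
  if (length(density) != length(bin_edges) - 1L)
    stop("need one density per bin")
  if (any(density < 0)) stop("densities must be non-negative")
  structure(list(bin_edges = bin_edges, density = density,
                 tissue_area_mm2 = tissue_area_mm2,
                 extinction_fraction = extinction_fraction),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat("<size_distribution> clusters per mm^2 tissue\n")
  lab <- paste0("[", head(x$bin_edges, -1L), ",", tail(x$bin_edges, -1L), ")")
  print(setNames(signif(x$density, 4), lab))
  if (!is.na(x$extinction_fraction))
    cat(sprintf("  extinction fraction: %.3f\n", x$extinction_fraction))
  invisible(x)
}

#' Seed an ensemble of disc patches from a fitted power law
#'
#' One quasi-circular disc patch per requested area, holding exactly
#' `round(x / delta^2)` mutant sites, each carrying the density weight
#' `y(x) = a * x^b` (clusters per mm^2 tissue). Weights are densities, not
#' counts: they scale each patch's contribution when composing predicted
#' distributions.
#'
#' @param fit a [fit_power_law()] result (or list with `a`, `b`).
#' @param area_grid ascending positive areas, um^2. The default covers
#'   25--20,000 um^2 with 20 log-spaced values.
#' @param delta lattice spacing, micrometres.
#' @return object of class `patch_ensemble`: list of entries with `area_um2`
#'   (realised, = site count * delta^2), `weight`, and `grid` (a `grid_state`).
#' @export
seed_patch_ensemble <- function(fit,
                                area_grid = exp(seq(log(25), log(20000),
                                                    length.out = 20)),
                                delta = 1) {
  area_grid <- as.numeric(area_grid)
  if (length(area_grid) == 0L)
    return(structure(list(), class = "patch_ensemble"))
  if (is.unsorted(area_grid) || any(area_grid <= 0))
    stop("`area_grid` must be positive and ascending")
  if (any(round(area_grid / delta^2) < 1))
    stop("patch area smaller than one lattice site")
  ens <- lapply(area_grid, function(x) {
    g <- disc_patch_grid(x, delta = delta)
    list(area_um2 = sum(g$occupancy) * delta^2,
         weight = predict_power_law(fit, x),
         grid = g)
  })
  structure(ens, class = "patch_ensemble")
}

#' @export
`[.patch_ensemble` <- function(x, i) {
  structure(unclass(x)[i], class = "patch_ensemble")
}

# deterministic per-(patch, replicate) seed; independent of d so that repeated
# objective evaluations reuse the same random numbers (CRN)
ensemble_seed <- function(base_seed, patch, replicate, n_replicates) {
  as.integer((base_seed + (patch - 1L) * n_replicates + (replicate - 1L)) %% .Machine$integer.max)
}

#' Predict the late-time cluster-size distribution of a patch ensemble
#'
#' Simulates every patch `n_replicates` times to `t_final` at rate `d` and
#' composes the predicted density-by-size curve as
#' \eqn{\sum_x w(x) \hat P(\text{final area bin} \mid x)}. Patches that go
#' extinct (area 0) are excluded from the bins and reported as a
#' density-weighted extinction fraction (set `include_extinct = TRUE` to count
#' them in the first bin instead).
#'
#' @param ensemble a [seed_patch_ensemble()] result.
#' @param d competition rate, per day.
#' @param t_final simulated time, days.
#' @param n_replicates trajectories per patch.
#' @param bins area bin edges, um^2.
#' @param seed base seed; per-(patch, replicate) seeds are derived from it.
#' @param include_extinct count extinct patches in the lowest bin?
#' @return a [size_distribution()]; attribute `"replicate_densities"` holds the
#'   per-replicate composed density matrix (replicates x bins) for Monte-Carlo
#'   error assessment.
#' @export
predict_final_distribution <- function(ensemble, d, t_final = 35,
                                       n_replicates = 20,
                                       bins = default_bin_edges(), seed = 1L,
                                       include_extinct = FALSE) {
  stopifnot(inherits(ensemble, "patch_ensemble"), n_replicates >= 1)
  nb <- length(bins) - 1L
  np <- length(ensemble)
  if (np == 0L) return(size_distribution(bins, rep(0, nb), extinction_fraction = NA))
  dens_rep <- matrix(0, n_replicates, nb)
  extinct_w <- 0
  total_w <- sum(vapply(ensemble, `[[`, numeric(1), "weight"))
  for (p in seq_len(np)) {
    ent <- ensemble[[p]]
    delta2 <- ent$grid$delta^2
    for (r in seq_len(n_replicates)) {
      pars <- simulation_params(d = d, t_final = t_final,
                                seed = ensemble_seed(seed, p, r, n_replicates),
                                snapshot_times = t_final)
      traj <- simulate_competition(ent$grid, pars)
      area <- traj$observables$mutant_count[1L] * delta2
      if (area == 0 && !include_extinct) {
        extinct_w <- extinct_w + ent$weight / n_replicates
      } else {
        b <- findInterval(area, bins, rightmost.closed = FALSE)
        b <- min(max(b, 1L), nb)
        dens_rep[r, b] <- dens_rep[r, b] + ent$weight
      }
    }
  }
  out <- size_distribution(bins, colMeans(dens_rep),
                           extinction_fraction = extinct_w / total_w)
  attr(out, "replicate_densities") <- dens_rep
  out
}

#' Calibrate the competition rate d against a target size distribution
#'
#' Minimises the least-squares distance between the predicted and target
#' binned densities over `d` in `d_bounds`, using common random numbers (the
#' same base seed for every evaluation) so the objective is deterministic in
#' `d`. A coarse grid scan brackets the optimum before Brent minimisation; the
#' best value over grid and refinement is returned.
#'
#' @param ensemble a [seed_patch_ensemble()] result.
#' @param target a [size_distribution()] on the same bins.
#' @param t_final simulated time, days.
#' @param n_replicates trajectories per patch per objective evaluation.
#' @param seed base seed shared by all evaluations (CRN).
#' @param d_bounds lower/upper bounds for d, per day.
#' @param n_grid points in the bracketing grid scan.
#' @param include_extinct passed to [predict_final_distribution()].
#' @return object of class `calibration_result`: list with `d_hat`,
#'   `objective`, `n_replicates`, `seed`, and `trace` (data frame of all
#'   evaluated `(d, objective)` pairs in evaluation order).
#' @export
calibrate_d <- function(ensemble, target, t_final = 35, n_replicates = 20,
                        seed = 1L, d_bounds = c(0, 0.5), n_grid = 8,
                        include_extinct = FALSE) {
  stopifnot(inherits(target, "size_distribution"))
  trace_d <- numeric(0); trace_obj <- numeric(0)
  objective <- function(d) {
    pred <- predict_final_distribution(ensemble, d, t_final = t_final,
                                       n_replicates = n_replicates,
                                       bins = target$bin_edges, seed = seed,
                                       include_extinct = include_extinct)
    val <- sum((pred$density - target$density)^2)
    trace_d <<- c(trace_d, d); trace_obj <<- c(trace_obj, val)
    val
  }
  grid <- seq(d_bounds[1], d_bounds[2], length.out = n_grid)
  gobj <- vapply(grid, objective, numeric(1))
  if (!any(is.finite(gobj)))
    stop("calibration failure: objective not finite anywhere in d_bounds")
  ibest <- which.min(gobj)
  lo <- grid[max(1L, ibest - 1L)]
  hi <- grid[min(n_grid, ibest + 1L)]
  opt <- optimize(objective, interval = c(lo, hi),
                  tol = max(diff(d_bounds) * 1e-3, 1e-5))
  cand_d <- c(trace_d); cand_obj <- c(trace_obj)
  best <- which.min(cand_obj)
  structure(list(d_hat = cand_d[best], objective = cand_obj[best],
                 n_replicates = n_replicates, seed = seed,
                 trace = data.frame(d = trace_d, objective = trace_obj)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> d_hat = %.5g /day (objective %.5g, %d evaluations)\n",
              x$d_hat, x$objective, nrow(x$trace)))
  invisible(x)
}

#' Mean boundary loss per day along a trajectory
#'
#' Quantifies the prediction that clusters shrink by losing a fixed fraction
#' of their mutant--normal boundary each day. For each whole-day interval
#' (k, k+1) present in the trajectory snapshots, computes either the fraction
#' of day-k boundary *cells* that are no longer mutant at day k+1
#' (`observable = "cells"`), or the fractional drop in boundary *edge* count
#' (`observable = "edges"`); returns the mean over days, times 100.
#'
#' @param trajectory a `competition_trajectory` whose snapshots include at
#'   least two consecutive whole days.
#' @param observable `"cells"` or `"edges"`.
#' @return percent of boundary lost per day.
#' @export
boundary_loss_per_day <- function(trajectory, observable = c("cells", "edges")) {
  observable <- match.arg(observable)
  obs <- trajectory$observables
  days <- obs$time_days
  is_day <- abs(days - round(days)) < 1e-9
  idx <- which(is_day)
  idx <- idx[order(days[idx])]
  if (length(idx) < 2L)
    stop("trajectory needs snapshots at >= 2 whole days")
  losses <- numeric(0)
  for (w in seq_len(length(idx) - 1L)) {
    k0 <- idx[w]; k1 <- idx[w + 1L]
    if (abs(days[k1] - days[k0] - 1) > 1e-9) next
    if (observable == "edges") {
      e0 <- obs$boundary_edges[k0]
      if (e0 == 0) stop("boundary is empty at the start of a day interval")
      losses <- c(losses, (e0 - obs$boundary_edges[k1]) / e0)
    } else {
      g0 <- trajectory$snapshots[[k0]]
      bm <- enumerate_contacts(g0)
      if (nrow(bm) == 0L) stop("boundary is empty at the start of a day interval")
      cells <- unique(bm[, c("m_i", "m_j")])
      occ1 <- trajectory$snapshots[[k1]]$occupancy
      gone <- occ1[as.matrix(cells)] == 0L
      losses <- c(losses, mean(gone))
    }
  }
  if (length(losses) == 0L) stop("no consecutive whole-day snapshot pair found")
  100 * mean(losses)
}
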