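# clonecomp

Stochastic lattice models and morphometry of clonal cell competition in
mosaic tissues.

When an activating oncogene (e.g. KrasG12D) is induced sparsely in an adult
epithelium, the labelled clones can be eliminated by their wild-type
neighbours over days to weeks: total labelled area falls, small clusters
vanish, and surviving clusters round up and compact before disappearing.
`clonecomp` is for quantitative biologists studying this process. It
implements the competition model, the calibration that links it to imaging
data, the image measurements that data consist of, and a synthetic
mosaic-tissue generator with exported ground truth for validating the whole
chain.

## The model

Cells occupy a square lattice with spacing δ (default 1 µm); every site is
either mutant *m* or wild-type *w*. Cells interact through shared faces
only (von Neumann neighbours), and the model has a single reaction: each
mutant-wild-type contact converts the mutant at rate *d* per day,

    m(i,j) + w(neighbour)  --d-->  w(i,j) + w(neighbour)

simulated exactly with the Gillespie stochastic simulation algorithm
(waiting time τ = ln(1/r₁)/a₀ with a₀ = d·n_contacts; cumulative-propensity
reaction selection). Mutants are eliminated only from cluster peripheries
and the mutant count declines monotonically; an isolated mutant survives an
Exponential(4d) lifetime, which anchors the analytic tests.

Around the simulator:

* `fit_power_law()` — nonlinear least squares for the cluster density–area
  law *y = a·xᵇ* (clusters per mm² tissue vs cluster area in µm²);
* `seed_patch_ensemble()` / `patch_ensemble_from_records()`,
  `predict_final_distribution()`, `calibrate_d()` — simulation-based
  calibration of *d* against late-time density-by-size tables, using common
  random numbers so the stochastic objective is deterministic in *d*;
* `segment_clusters()`, `density_by_size()`, `circularity()`,
  `sphericity_index()`, `build_cell_graph()`, `internuclear_distances()`,
  `cell_volume()`, `label_area_fraction()`, `interface_intensity()`,
  `cells_per_cluster()` — morphometry of labelled tissue images;
* `generate_mosaic()`, `generate_cell_packing()`, `render_channels()`,
  `generate_time_series()` — synthetic data with ground truth;
* `run_pipeline()` — JSON-configured end-to-end runs with a checksummed
  manifest.

## Worked example

Simulate a 2,000 µm² mutant patch embedded in normal tissue for 35 days at
*d* = 0.1/day and inspect the shrinkage:

```r
library(clonecomp)

patch  <- disc_patch_grid(area = 2000)            # digital disc, 2000 sites
params <- simulation_params(d = 0.1, t_final = 35, seed = 1,
                            snapshot_times = 0:35)
traj   <- simulate_competition(patch, params)
traj$observables[traj$observables$time_days %in% c(0, 7, 21, 35), ]
#>    time_days mutant_count boundary_cells boundary_edges
#> 1          0         2000            140            204
#> 8          7         1809            170            280
#> 22        21         1441            158            252
#> 36        35         1102            149            250

boundary_loss_per_day(traj, "cells")
#> [1] 14.71812
```

The patch loses ~45% of its area over 35 days. About 14.7% of each day's
boundary cells are converted per day in this run: boundary cells on a rough
shrinking cluster carry more than one wild-type contact on average, so the
per-cell loss exceeds the single-contact hazard 1 − e⁻ᵈ ≈ 9.5%; the
boundary *edge* count meanwhile stays nearly stationary as the cluster
shrinks (both observables are available).

Fitting the density–area power law to noiseless points sampled from the
reference seven-day curve (a = 2436, b = −1.067) recovers its coefficients
exactly:

```r
pts <- data.frame(x = exp(seq(log(100), log(20000), length.out = 200)))
pts$y <- 2436 * pts$x^-1.067
fit_power_law(pts)
#> <power_law_fit> y = a * x^b
#>   a = 2436  (95% CI 2436 - 2436)
#>   b = -1.067  (95% CI -1.067 - -1.067)
#>   rss = 2.4e-21 over 200 points
```

An end-to-end recovery — generate a mosaic at 20% labelling, simulate its
shrinkage at a known rate, then calibrate the rate back from the emitted
35-day density table — is in `tests/testthat/test-acceptance.R` and
recovers *d* = 0.1 within a few percent.

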