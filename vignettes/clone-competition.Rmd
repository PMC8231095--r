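---
title: "Modelling and measuring clonal cell competition in mosaic tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring clonal cell competition in mosaic tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecomp)
```

## The problem

In mosaic epithelia, sparse clones carrying an activating oncogene (the
motivating system is KrasG12D in adult mouse pancreas, lineage-labelled with
RFP) can be *outcompeted* by their normal neighbours: over weeks the labelled
area shrinks, small clusters disappear, and the surviving clusters become
rounder and more tightly packed before elimination. `clonecomp` provides the
three computational pieces needed to study this process quantitatively:

1. a stochastic lattice model of mutant-normal competition with an exact
   Gillespie simulator,
2. calibration machinery that links the model to cluster density-by-size
   data through the density-area power law, and
3. labelled-image morphometrics plus a synthetic mosaic-tissue generator
   whose exported ground truth closes the loop on every measurement.

## The competition model

Cells live on a square lattice with spacing $\delta$ (default 1 µm,
configurable); each site is occupied by exactly one cell, mutant ($m$) or
wild-type ($w$). Cells interact only through shared faces (von Neumann
neighbourhood: north, east, south, west). The model has a single reaction
type: a mutant site with a wild-type neighbour is replaced by wild-type at
rate $d$ (day$^{-1}$) *per contact*,

$$ m_{(i,j)} + w_{(i\pm1,j)\,\text{or}\,(i,j\pm1)}
   \;\xrightarrow{\;d\;}\; w + w. $$

There is no mutant birth, no death away from the interface, and no movement,
so the mutant population declines monotonically and cells are eliminated only
from the cluster periphery, irrespective of cluster size. An isolated mutant
(4 contacts) dies after an Exponential($4d$) waiting time; this closed form is
the main analytic oracle in the test suite.

Trajectories are sampled exactly with the direct-method stochastic simulation
algorithm: with $n$ contacts the total propensity is $a_0 = d\,n$, the
waiting time is $\tau = \ln(1/r_1)/a_0$, and the fired reaction is the first
index whose cumulative propensity fraction exceeds $r_2$. Numerical
conventions, chosen once:

* **Reaction indexing.** Contacts are enumerated row-major by mutant site,
  then N, E, S, W by neighbour. With equal propensities the cumulative search
  reduces to $\lfloor r_2 n \rfloor + 1$, which both engines use verbatim so
  selection is reproducible to the bit.
* **$r_1 = 0$ guard.** $\ln(1/r_1)$ diverges at 0; draws of exactly 0 are
  rejected and redrawn (R's generator cannot actually return 0, so the guard
  never consumes extra variates in practice).
* **Horizon.** An event whose waiting time would carry $t$ past `t_final` is
  not fired; since every requested snapshot lies at or before `t_final`, the
  recorded output is identical to the fire-then-stop convention.
* **Snapshots.** The state at snapshot time $t$ is the state after all events
  with event time $\le t$ (the process is piecewise constant).
* **Boundaries.** `wildtype_frame` (default) surrounds the lattice with an
  infinite wild-type sea, matching a mutant patch embedded in normal tissue;
  `periodic_x` wraps columns and closes rows (used for flat-interface
  experiments); `periodic_xy` wraps both (used for analytic absorbing-state
  tests).
* **Engines.** The compiled engine maintains the contact set incrementally in
  a Fenwick tree (only the fired site's neighbourhood changes); the pure-R
  engine re-enumerates contacts from scratch every step. Both consume the RNG
  stream identically and the suite asserts bit-identical event sequences.
* **Seeds.** One seeded generator drives everything; replicate $k$ of patch
  $p$ uses `seed + (p-1)*n_replicates + (k-1)`, so ensembles are reproducible
  and common random numbers are available for calibration.

```{r}
patch <- disc_patch_grid(area = 2000)  # 2,000 um^2 disc in a wild-type sea
params <- simulation_params(d = 0.1, t_final = 35, seed = 1,
                            snapshot_times = 0:35)
traj <- simulate_competition(patch, params)
tail(traj$observables, 3)
```

## Boundary loss per day: cells versus edges

The model predicts that clusters shrink by losing a fixed fraction of their
mutant-normal boundary each day. "Boundary" can be read two ways, and both
observables are exposed: boundary *cells* (mutant sites with at least one
wild-type neighbour) and boundary *edges* (mutant-wild-type face pairs, the
interface length). `boundary_loss_per_day()` computes, for each whole-day
interval, either the fraction of day-$k$ boundary cells no longer mutant at
day $k{+}1$, or the fractional change in edge count.

Two facts about these observables are worth keeping straight, both computed
by the test suite rather than assumed:

* On a **flat interface** where every boundary cell starts with exactly one
  contact, the first-order hazard gives a daily conversion of $1 - e^{-d}$;
  at $d = 0.01$/day the simulated value matches 1.0% to within 0.02
  percentage points. At larger rates the interface roughens *during* the
  day -- a tracked cell's neighbours convert and expose it to second and
  third contacts -- so the realised conversion exceeds the first-order value.
  At $d = -\ln(0.9) \approx 0.105$/day (the rate whose first-order hazard is
  exactly 10%/day) the exact model converts about 11.1% of initially
  interface-adjacent cells per day. The package reports the exact simulated
  value.
* On a **shrinking rough cluster**, boundary cells carry more than one
  contact on average, so per-cell conversion is higher still, while the edge
  count can stay nearly stationary as the cluster shrinks.

## The density-area power law and calibration of $d$

Early-time cluster data enter the model as a density-area curve
$y = a\,x^b$ (clusters per mm$^2$ tissue against cluster area in µm$^2$).
`fit_power_law()` minimises $\sum_i (y_i - a x_i^b)^2$ on the *linear*
densities by Levenberg-Marquardt from the neutral start $(a{=}1, b{=}-0.5)$,
with 95% CIs from the local-linearisation covariance. A log-space variant is
provided but is not the default. One statistical caveat, measured in the
suite: under multiplicative (constant relative) noise the linear-space
linearisation CIs under-cover (about 75% observed at 5% noise), because the
noise is heteroscedastic relative to the implicit homoscedastic assumption;
the log-space fit is variance-matched for that noise model and covers at the
nominal rate. Point estimates of the linear fit remain accurate in both
cases; choose the space to match your error model when the CIs matter.

Calibration proceeds by forward simulation: seed an ensemble of
quasi-circular disc patches (exact pixel count $\mathrm{round}(x/\delta^2)$,
nearest-to-centre sites, deterministic tie-break by row then column), carry
each patch's density weight, simulate to 35 days, bin the surviving areas,
and choose $d$ so the predicted density-by-size curve best fits the observed
late-time curve in the least-squares sense. Two ensemble seedings are
available:

* `seed_patch_ensemble()` -- areas on a log-spaced grid (default 20 areas,
  25-20,000 µm$^2$), weights $y(x) = a x^b$ from the fitted law, per the
  model description;
* `patch_ensemble_from_records()` -- one patch per *observed* cluster with
  weight $1/\text{tissue area}$, which makes predictions dimensionally
  commensurable with measured density tables and is what the end-to-end
  recovery test uses.

`calibrate_d()` uses common random numbers (the same derived seeds at every
evaluation) so the Monte-Carlo objective is a deterministic function of $d$,
then brackets with a coarse grid and refines by Brent minimisation. Because
binned areas make the objective piecewise constant in $d$, unimodality is a
local property around the optimum (asserted there in the suite), and the
returned $d$ is the best over all evaluations. Extinct patches are excluded
from the bins and reported as an extinction fraction (`include_extinct`
counts them in the lowest bin instead; whether the original analysis included
them is not stated). Size bins default to
$[0, 500, 1000, 2000, 5000, 10000, 20000, \infty)$ µm$^2$, anchored at the
2,000 µm$^2$ small-cluster threshold; they are fully configurable.

## Morphometry

All measurements work on `label_image` containers (2D or 3D integer arrays
with per-axis physical spacing; coordinates are 0-based row/col[/plane] and
every output is in physical units).

* `segment_clusters()` -- connected components, 4-connectivity by default
  (consistent with the model's von Neumann adjacency), 8 by flag, face
  connectivity in 3D; `min_area` filtering; areas are pixel count x pixel
  area.
* **Perimeter and circularity.** Circularity is $4\pi A / P^2$ with the
  perimeter estimated by the 4-direction Crofton formula
  $\hat P = \tfrac{\pi}{8}(I_h h + I_v h + (I_{d1}+I_{d2})h/\sqrt2)$ from
  intercept counts along rows, columns and both diagonals. Pixel-edge
  counting (`method = "edge"`) biases digital discs to about 0.79; the
  Crofton estimate approaches the continuum value (0.99 at radius 50 px).
  The classic worked example -- an $n \times n$ square with naive edge-count
  perimeter $4n$ -- gives exactly $\pi/4$. Discretisation can push raw
  scores slightly above 1, so the returned value is clamped at 1 with the
  raw value kept as an attribute.
* **Sphericity index.** Imaging software packages differ in how they score
  boundary smoothness, so the package documents its own convention
  prominently: the ratio
  of the convex-hull perimeter of the object's pixel centres to the Crofton
  boundary perimeter, in $(0,1]$; smooth convex boundaries score near 1,
  lobed boundaries lower, a single pixel scores 1 by definition.
* `build_cell_graph()` -- cells sharing at least one face-adjacent pixel
  pair are neighbours; each edge stores its interface pixels and a class
  (clone-clone / clone-normal / normal-normal) from the cells' clone flags.
  At junction pixels classes overlap; each pixel is assigned the
  highest-precedence class (clone-normal > clone-clone > normal-normal) and
  `interface_intensity()` quantifies a pixel only under that class, so
  channel rendering and measurement agree exactly in the noiseless case.
* `internuclear_distances()` (Euclidean, physical units, optionally
  restricted to clone cells in direct contact), `cell_volume()` (voxel count
  x voxel volume), `label_area_fraction()` (percent of tissue covered by
  label), `cells_per_cluster()` (clone cells assigned to clusters by pixel
  overlap; a cell overlapping two clusters is a contract violation).

## What the synthetic generator emulates -- and what it does not

`generate_mosaic()` draws cluster areas i.i.d. from the truncated power-law
density $\propto x^b$ on [25, 20,000] µm$^2$ by inverse-CDF sampling and
places disc-shaped clusters uniformly without overlap (with a minimum gap so
segmentation keeps them discrete) until the target labelled fraction
(default 20%, emulating low-dose induction) is reached within one percentage
point. A sampling note: the density curve is converted to a generator by
normalising it to a probability density and stopping at target coverage,
rather than by drawing per-bin Poisson counts -- coverage, not expected
count, is the generator's contract, and the realised size law is identical
(Kolmogorov-Smirnov checked in the suite).

`generate_cell_packing()` tessellates the tissue by region-restricted
Voronoi assignment of jittered-lattice seed points -- seed spacing equals the
mean cell diameter outside clones and `compaction` times that inside, so
within-clone internuclear distance scales with the compaction factor (the
tighter packing of mutant clusters becomes a tunable effect). Restricting
assignment to each cluster's own seeds guarantees cells never straddle
cluster boundaries. `render_channels()` paints interface pixels at a base
intensity, attenuates clone-normal interfaces by a factor $f$ (emulating
reduced junctional E-cadherin at mutant-normal contacts), and adds optional
Poisson shot noise and Gaussian read noise. `generate_time_series()` runs
the competition model per cluster and emits day-stamped areas and
density-by-size tables with the generating $d$ recorded as truth.

The generator reproduces the *statistical structure* the pipeline needs --
size laws, coverage, adjacency, compaction, interface attenuation,
shrinkage dynamics -- not microscopy: there is no point-spread function, no
real segmentation problem (ground-truth labels are exported, not detected),
no anatomical realism (ducts, islets), and no 3D serial-section artefacts.
Passing the round-trip tests therefore demonstrates that the measurement
code is correct on data whose truth is known, not that upstream raw-image
segmentation of real tissue would be error-free.

## Problem sizes

The test suite and acceptance script use sizes chosen to make Monte-Carlo
error small relative to the tolerances they assert: 10,000 replicates for
the survival oracle, 200 seeds on a 512 x 64 flat interface for boundary
loss, a 1,024$^2$ µm mosaic (about 100 clusters) with 3 replicate time
series and 4 calibration replicates per objective evaluation for the
end-to-end rate recovery, and 100 random lattices for the structural
invariants. All are package choices and scale linearly if more precision is
wanted.

## Known limitations

* The model has exactly one reaction: no mutant proliferation, apoptosis
  fields, mechanics, or movement, and no hexagonal/off-lattice geometry. A
  lattice site is one model "cell" of area $\delta^2$; the biological
  mapping of $\delta$ is left to the user.
* Calibration provides no confidence interval for $\hat d$ (the procedure
  defines none); the recovery tests characterise its sampling
  error empirically (median relative error below 15% under the study
  conditions).
* Circularity and sphericity conventions are this package's documented
  choices among several in circulation (ImageJ- and Imaris-style scores
  differ in detail); comparisons across software should use the formulas
  stated here.
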