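test_that("patch ensembles carry exact disc sizes and power-law weights", {
  fit <- list(a = 2436, b = -1.067)
  expect_length(seed_patch_ensemble(fit, area_grid = numeric(0)), 0L)
  ens <- seed_patch_ensemble(fit, area_grid = c(25, 100, 2000))
  expect_identical(vapply(ens, function(e) sum(e$grid$occupancy), integer(1)),
                   as.integer(round(c(25, 100, 2000))))
  expect_equal(vapply(ens, `[[`, numeric(1), "weight"),
               2436 * c(25, 100, 2000)^-1.067)
  expect_error(seed_patch_ensemble(fit, area_grid = 0.2),
               "smaller than one lattice site")
})

test_that("predicted distribution at d = 0 equals the initial ensemble binned", {
  ens <- seed_patch_ensemble(list(a = 100, b = -1),
                             area_grid = c(100, 700, 1500, 3000))
  pred <- predict_final_distribution(ens, d = 0, n_replicates = 3, seed = 5)
  e <- default_bin_edges()
  init <- vapply(seq_len(length(e) - 1L), function(b) {
    sum(vapply(ens, function(en)
      en$weight * (en$area_um2 >= e[b] && en$area_um2 < e[b + 1]), numeric(1)))
  }, numeric(1))
  expect_equal(pred$density, init)
  expect_equal(pred$extinction_fraction, 0)
})

test_that("total predicted density never exceeds the initial density and large d is absorbing", {
  ens <- seed_patch_ensemble(list(a = 50, b = -1), area_grid = c(30, 60, 120))
  init_total <- sum(vapply(ens, `[[`, numeric(1), "weight"))
  for (d in c(0, 0.05, 0.3)) {
    pred <- predict_final_distribution(ens, d, t_final = 35, n_replicates = 10,
                                       seed = 9)
    expect_lte(sum(pred$density), init_total + 1e-12)
  }
  # all replicates extinct: empty distribution, extinction fraction 1
  pred <- predict_final_distribution(ens[1], d = 5, t_final = 35,
                                     n_replicates = 10, seed = 9)
  expect_true(all(pred$density == 0))
  expect_equal(pred$extinction_fraction, 1)
})

test_that("Monte-Carlo error of the prediction shrinks like 1/sqrt(n)", {
  ens <- seed_patch_ensemble(list(a = 300, b = -1),
                             area_grid = exp(seq(log(50), log(2000),
                                                 length.out = 6)))
  se_of <- function(n) {
    pred <- predict_final_distribution(ens, d = 0.08, t_final = 20,
                                       n_replicates = n, seed = 17)
    reps <- attr(pred, "replicate_densities")
    mean(apply(reps, 2, sd)) / sqrt(n)
  }
  ratio <- se_of(50) / se_of(200)
  expect_gt(ratio, 1.4)  # ideal 2; allow Monte-Carlo slack
  expect_lt(ratio, 2.9)
})

test_that("calibration recovers the generating rate and hits the zero bound", {
  ens <- seed_patch_ensemble(list(a = 800, b = -1),
                             area_grid = exp(seq(log(50), log(3000),
                                                 length.out = 8)))
  # target generated from the ensemble itself at d = 0 -> d_hat at lower bound
  target0 <- predict_final_distribution(ens, 0, t_final = 20,
                                        n_replicates = 5, seed = 301)
  cal0 <- calibrate_d(ens, target0, t_final = 20, n_replicates = 5,
                      seed = 302, d_bounds = c(0, 0.3), n_grid = 5)
  expect_identical(cal0$d_hat, 0)
  # recovery across rates with independent seeds, median error <= 15%
  errs <- vapply(c(0.05, 0.1, 0.2), function(d_true) {
    target <- predict_final_distribution(ens, d_true, t_final = 20,
                                         n_replicates = 40, seed = 310)
    cal <- calibrate_d(ens, target, t_final = 20, n_replicates = 15,
                       seed = 411, d_bounds = c(0, 0.4), n_grid = 6)
    abs(cal$d_hat - d_true) / d_true
  }, numeric(1))
  expect_lte(median(errs), 0.15)
})

test_that("the common-random-number objective is unimodal around its optimum", {
  ens <- seed_patch_ensemble(list(a = 800, b = -1),
                             area_grid = exp(seq(log(50), log(3000),
                                                 length.out = 8)))
  target <- predict_final_distribution(ens, 0.1, t_final = 20,
                                       n_replicates = 30, seed = 55)
  dgrid <- seq(0.05, 0.15, length.out = 10)  # window around the optimum
  obj <- vapply(dgrid, function(d) {
    pred <- predict_final_distribution(ens, d, t_final = 20, n_replicates = 10,
                                       seed = 66)
    sum((pred$density - target$density)^2)
  }, numeric(1))
  imin <- which.min(obj)
  expect_true(all(diff(obj[seq_len(imin)]) <= 1e-9))
  expect_true(all(diff(obj[imin:length(obj)]) >= -1e-9))
})

test_that("boundary loss per day matches the single-contact hazard at small d", {
  # d = 0: nothing converts
  g <- flat_interface_grid(64, 8, 8)
  tr0 <- simulate_competition(g, simulation_params(0, 2, seed = 1,
                                                   snapshot_times = c(0, 1, 2)))
  expect_equal(boundary_loss_per_day(tr0, "cells"), 0)
  expect_equal(boundary_loss_per_day(tr0, "edges"), 0)
  # d = 0.01/day on a flat interface: per-day conversion ~ 1 - exp(-0.01)
  d <- 0.01
  losses <- vapply(1:500, function(s) {
    tr <- simulate_competition(
      flat_interface_grid(256, 16, 16),
      simulation_params(d, 1, seed = s, snapshot_times = c(0, 1)))
    boundary_loss_per_day(tr, "cells")
  }, numeric(1))
  expect_lt(abs(mean(losses) - 100 * (1 - exp(-d))), 0.2)
  # empty boundary is an error
  tr_empty <- simulate_competition(
    grid_state(matrix(0L, 4, 4)),
    simulation_params(0.1, 2, seed = 1, snapshot_times = c(0, 1, 2)))
  expect_error(boundary_loss_per_day(tr_empty, "cells"), "empty")
})
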