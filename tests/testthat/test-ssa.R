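test_that("contact enumeration matches hand counts and fixed ordering", {
  # all wild-type: nothing to fire
  expect_identical(nrow(enumerate_contacts(grid_state(matrix(0L, 4, 4)))), 0L)
  # single interior mutant: 4 reactions, N/E/S/W order
  occ <- matrix(0L, 5, 5); occ[3, 3] <- 1L
  ct <- enumerate_contacts(grid_state(occ))
  expect_identical(nrow(ct), 4L)
  expect_identical(ct$dir, 1:4)
  expect_identical(ct$n_i, c(2L, 3L, 4L, 3L))
  expect_identical(ct$n_j, c(3L, 4L, 3L, 2L))
  # 2x2 mutant block: each cell has 2 WT neighbours -> 8 reactions
  occ <- matrix(0L, 6, 6); occ[3:4, 3:4] <- 1L
  ct <- enumerate_contacts(grid_state(occ))
  expect_identical(nrow(ct), 8L)
  # row-major by mutant site, then N,E,S,W
  key <- (ct$m_i - 1) * 6 + (ct$m_j - 1)
  expect_true(!is.unsorted(key))
  expect_true(all(tapply(ct$dir, key, function(d) !is.unsorted(d))))
})

test_that("off-grid neighbours follow the boundary mode", {
  one <- grid_state(matrix(1L, 1, 1))  # wildtype_frame: 4 frame contacts
  ct <- enumerate_contacts(one)
  expect_identical(nrow(ct), 4L)
  expect_true(all(is.na(ct$n_i)))
  # periodic_xy all-mutant: wrapping neighbours are mutant -> absorbing
  expect_identical(nrow(enumerate_contacts(
    grid_state(matrix(1L, 4, 4), boundary = "periodic_xy"))), 0L)
  # periodic_x: columns wrap, rows are closed
  occ <- matrix(0L, 2, 3); occ[1, 1] <- 1L
  ct <- enumerate_contacts(grid_state(occ, boundary = "periodic_x"))
  expect_identical(nrow(ct), 3L)          # E, S, W (wrapped); no N
  expect_identical(sort(ct$dir), c(2L, 3L, 4L))
  expect_identical(ct$n_j[ct$dir == 4L], 3L)  # W wraps to last column
})

test_that("draw_step reproduces the printed waiting-time and selection rules", {
  occ <- matrix(0L, 5, 5); occ[3, 3] <- 1L
  ct <- enumerate_contacts(grid_state(occ))
  s <- draw_step(ct, d = 1, r1 = 0.5, r2 = 0.6)
  expect_equal(s$a0, 4)
  expect_equal(s$tau, log(2) / 4)             # tau = ln(1/r1)/a0
  expect_identical(s$fired_index, 3L)         # cumulative fractions .25/.5/.75/1
  expect_identical(draw_step(ct, 1, 0.5, 0)$fired_index, 1L)
  expect_identical(draw_step(ct, 1, 0.5, 1)$fired_index, 4L)  # clamped
  expect_error(draw_step(ct, 1, 0, 0.5), "r1")
  # empty contact set signals the absorbing state
  empty <- enumerate_contacts(grid_state(matrix(0L, 3, 3)))
  expect_error(draw_step(empty, 1, 0.5, 0.5), class = "absorbing_state")
})

test_that("apply_reaction flips exactly the mutant site and conserves sites", {
  occ <- matrix(0L, 6, 6); occ[3:4, 3:4] <- 1L
  g <- grid_state(occ)
  ct <- enumerate_contacts(g)
  g2 <- apply_reaction(g, ct[1L, ])
  expect_identical(sum(g2$occupancy), 3L)                       # L-tromino left
  expect_identical(length(g2$occupancy), length(g$occupancy))   # conservation
  changed <- which(g2$occupancy != g$occupancy, arr.ind = TRUE)
  expect_identical(nrow(changed), 1L)
  expect_identical(as.integer(changed), c(ct$m_i[1L], ct$m_j[1L]))
  # firing the same reaction twice is a contract violation
  expect_error(apply_reaction(g2, ct[1L, ]), "stale")
  # removing the last mutant empties the grid
  solo <- grid_state(rbind(c(0L, 0L), c(0L, 1L)))
  ct1 <- enumerate_contacts(solo)
  expect_identical(sum(apply_reaction(solo, ct1[1L, ])$occupancy), 0L)
})

test_that("boundary metrics count periphery cells and interface edges", {
  occ <- matrix(0L, 7, 7); occ[3:5, 3:5] <- 1L  # 3x3 square
  bm <- boundary_metrics(grid_state(occ))
  expect_identical(unname(bm["boundary_cells"]), 8L)
  expect_identical(unname(bm["boundary_edges"]), 12L)
  expect_identical(unname(boundary_metrics(grid_state(matrix(1L, 1, 1)))), c(1L, 4L))
  expect_identical(
    unname(boundary_metrics(grid_state(matrix(1L, 3, 3), boundary = "periodic_xy"))),
    c(0L, 0L))
})

test_that("simulation is deterministic under a seed and inert at d = 0", {
  g <- random_grid(8, 8, 0.4)
  p <- simulation_params(d = 0.5, t_final = 4, seed = 13, snapshot_times = c(0, 2, 4))
  t1 <- simulate_competition(g, p, record_events = TRUE)
  t2 <- simulate_competition(g, p, record_events = TRUE)
  expect_identical(t1$observables, t2$observables)
  expect_identical(t1$events, t2$events)
  p0 <- simulation_params(d = 0, t_final = 4, seed = 13, snapshot_times = c(0, 4))
  tr0 <- simulate_competition(g, p0)
  for (s in tr0$snapshots) expect_identical(s$occupancy, g$occupancy)
})

test_that("incremental (C) and re-enumerating (R) engines agree event for event", {
  set.seed(202)
  for (b in c("wildtype_frame", "periodic_x", "periodic_xy")) {
    g <- random_grid(7, 9, 0.5, boundary = b)
    p <- simulation_params(d = 0.6, t_final = 3, seed = 31,
                           snapshot_times = c(0, 0.5, 1.7, 3))
    a <- simulate_competition(g, p, engine = "C", record_events = TRUE)
    r <- simulate_competition(g, p, engine = "R", record_events = TRUE)
    expect_identical(a$observables, r$observables)
    expect_equal(as.data.frame(a$events), r$events, ignore_attr = TRUE)
    for (k in seq_along(a$snapshots))
      expect_identical(a$snapshots[[k]]$occupancy, r$snapshots[[k]]$occupancy)
  }
})

test_that("snapshot state is the state after all events at or before its time", {
  g <- grid_state(matrix(1L, 1, 1))
  p <- simulation_params(d = 5, t_final = 10, seed = 3,
                         snapshot_times = c(0, 10))
  tr <- simulate_competition(g, p, record_events = TRUE)
  tev <- tr$events$time_days[1L]
  expect_identical(tr$observables$mutant_count, c(1L, 0L))
  # a snapshot placed exactly at the event time includes the event
  p2 <- simulation_params(d = 5, t_final = 10, seed = 3,
                          snapshot_times = c(tev, 10))
  tr2 <- simulate_competition(g, p2)
  expect_identical(tr2$observables$mutant_count, c(0L, 0L))
})

test_that("trajectory export carries the documented columns", {
  g <- random_grid(6, 6, 0.3)
  tr <- simulate_competition(g, simulation_params(0.2, 2, seed = 8,
                                                  snapshot_times = c(0, 1, 2)))
  path <- tempfile(fileext = ".csv")
  out <- write_trajectory(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_days", "mutant_count", "boundary_cells",
                     "boundary_edges", "n_clusters"))
  expect_identical(nrow(df), 3L)
  expect_true(all(df$n_clusters >= 0))
})
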