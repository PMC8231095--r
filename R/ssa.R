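# Gillespie simulation of the lattice competition model.
#
# The only reaction in the model replaces a mutant site that touches a
# wild-type von Neumann neighbour by wild-type, at rate d per (mutant, WT)
# contact. enumerate_contacts/draw_step/apply_reaction expose the individual
# SSA steps; simulate_competition() runs whole trajectories through a compiled
# engine that maintains the contact set incrementally (and, for verification,
# through a pure-R engine that re-enumerates contacts from scratch each step).

# direction codes: 1 = N (row - 1), 2 = E (col + 1), 3 = S (row + 1), 4 = W (col - 1)
DIR_DELTA <- matrix(c(-1L, 0L, 0L, 1L, 1L, 0L, 0L, -1L), nrow = 4L, byrow = TRUE)

#' Enumerate all mutant--wild-type contact reactions on a grid
#'
#' One reaction per ordered (mutant site, wild-type neighbour) pair: a mutant
#' with k wild-type von Neumann neighbours contributes k reactions, each firing
#' at propensity `d`. Reactions are listed row-major by mutant site and then in
#' N, E, S, W order, which fixes the indexing used by [draw_step()]. Under the
#' `wildtype_frame` boundary, off-grid neighbours count as wild-type (rows
#' `n_i`/`n_j` are `NA` for such frame contacts); under periodic boundaries
#' neighbours wrap.
#'
#' @param grid a [grid_state()].
#' @return data frame with columns `m_i`, `m_j` (mutant site), `n_i`, `n_j`
#'   (wild-type neighbour, `NA` = off-grid frame) and `dir` (1=N, 2=E, 3=S, 4=W).
#' @export
enumerate_contacts <- function(grid) {
  stopifnot(inherits(grid, "grid_state"))
  occ <- grid$occupancy
  nr <- nrow(occ); nc <- ncol(occ)
  bnd <- grid$boundary
  M <- occ == 1L
  rows <- seq_len(nr); cols <- seq_len(nc)
  # per direction: is the neighbour wild-type (off-grid frame counts as WT),
  # plus the neighbour coordinate grids (NA for off-grid frame neighbours)
  per_dir <- function(dir) {
    dr <- DIR_DELTA[dir, 1L]; dc <- DIR_DELTA[dir, 2L]
    ni <- rows + dr; nj_ <- cols + dc
    wrap_r <- bnd == "periodic_xy"
    wrap_c <- bnd %in% c("periodic_x", "periodic_xy")
    ri <- if (wrap_r) ((ni - 1L) %% nr) + 1L else ni
    cj <- if (wrap_c) ((nj_ - 1L) %% nc) + 1L else nj_
    r_in <- ri >= 1L & ri <= nr
    c_in <- cj >= 1L & cj <= nc
    valid <- outer(r_in, c_in, `&`)          # neighbour exists on-grid
    ri_c <- pmin(pmax(ri, 1L), nr); cj_c <- pmin(pmax(cj, 1L), nc)
    wt <- matrix(FALSE, nr, nc)
    wt[valid] <- occ[ri_c, cj_c, drop = FALSE][valid] == 0L
    if (bnd == "wildtype_frame") wt[!valid] <- TRUE  # frame is wild-type
    ni_mat <- matrix(ri_c, nr, nc); nj_mat <- matrix(cj_c, nr, nc, byrow = TRUE)
    ni_mat[!valid] <- NA_integer_; nj_mat[!valid] <- NA_integer_
    contact <- M & wt
    sel <- which(contact)
    if (length(sel) == 0L) return(NULL)
    i <- ((sel - 1L) %% nr) + 1L
    j <- ((sel - 1L) %/% nr) + 1L
    data.frame(m_i = i, m_j = j, n_i = ni_mat[sel], n_j = nj_mat[sel],
               dir = dir)
  }
  parts <- do.call(rbind, lapply(1:4, per_dir))
  if (is.null(parts)) {
    return(data.frame(m_i = integer(), m_j = integer(), n_i = integer(),
                      n_j = integer(), dir = integer()))
  }
  key <- ((parts$m_i - 1) * nc + (parts$m_j - 1)) * 4 + parts$dir
  parts <- parts[order(key), , drop = FALSE]
  rownames(parts) <- NULL
  parts
}

#' Draw one SSA step: waiting time and fired reaction
#'
#' Implements the direct-method update. With total propensity
#' \eqn{a_0 = d \cdot n_{contacts}}, the waiting time is
#' \eqn{\tau = \ln(1/r_1)/a_0} and the fired reaction is the first index whose
#' cumulative propensity fraction exceeds \eqn{r_2}; with equal propensities
#' this is \eqn{\lfloor r_2 n \rfloor + 1} in enumeration order. `r1 = 0`
#' (where the waiting-time formula diverges) is rejected: callers drawing from
#' a U(0,1) generator should redraw, as [simulate_competition()] does.
#'
#' @param contacts data frame from [enumerate_contacts()].
#' @param d competition rate per contact, per day.
#' @param r1,r2 uniform variates; `r1` in (0, 1], `r2` in [0, 1].
#' @return list with `a0` (total propensity, per day), `tau` (days) and
#'   `fired_index` (row of `contacts`), or an "absorbing state" condition if no
#'   contact exists.
#' @export
draw_step <- function(contacts, d, r1, r2) {
  n <- nrow(contacts)
  if (n == 0L || d <= 0) {
    stop(structure(class = c("absorbing_state", "error", "condition"),
                   list(message = "absorbing state reached: no mutant-wild-type contact",
                        call = sys.call(-1))))
  }
  if (r1 <= 0 || r1 > 1) stop("r1 must lie in (0, 1]")
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  a0 <- d * n
  fired <- min(floor(r2 * n) + 1, n)
  list(a0 = a0, tau = log(1 / r1) / a0, fired_index = as.integer(fired))
}

#' Apply one fired contact reaction to a grid
#'
#' The mutant site of the reaction becomes wild-type; every other site is
#' unchanged, so the total site count is conserved.
#'
#' @param grid a [grid_state()].
#' @param reaction one row of the data frame from [enumerate_contacts()].
#' @return the updated `grid_state`.
#' @export
apply_reaction <- function(grid, reaction) {
  stopifnot(inherits(grid, "grid_state"))
  i <- reaction$m_i[1L]; j <- reaction$m_j[1L]
  if (grid$occupancy[i, j] != 1L)
    stop(sprintf("stale reaction: site (%d, %d) is no longer mutant", i, j))
  grid$occupancy[i, j] <- 0L
  grid
}

#' Mutant--wild-type boundary observables
#'
#' `boundary_cells` counts mutant sites with at least one wild-type von Neumann
#' neighbour (cells on the cluster periphery); `boundary_edges` counts
#' mutant--wild-type adjacent pairs, i.e. the interface length in lattice edges
#' (equal to the number of contact reactions).
#'
#' @param grid a [grid_state()].
#' @return named numeric vector `c(boundary_cells, boundary_edges)`.
#' @export
boundary_metrics <- function(grid) {
  contacts <- enumerate_contacts(grid)
  cells <- if (nrow(contacts)) nrow(unique(contacts[, c("m_i", "m_j")])) else 0L
  c(boundary_cells = as.integer(cells), boundary_edges = nrow(contacts))
}

#' Simulation parameters for the competition model
#'
#' @param d competition rate per mutant--wild-type contact, per day (>= 0).
#' @param t_final end time in days (> 0).
#' @param seed RNG seed (integer).
#' @param snapshot_times ascending unique times in `[0, t_final]` (days) at
#'   which the lattice state is recorded.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(d, t_final = 35, seed = 1L,
                              snapshot_times = c(0, t_final)) {
  if (!is.numeric(d) || d < 0) stop("`d` must be >= 0")
  if (!is.numeric(t_final) || t_final <= 0) stop("`t_final` must be > 0")
  snapshot_times <- as.numeric(snapshot_times)
  if (is.unsorted(snapshot_times, strictly = TRUE))
    stop("`snapshot_times` must be strictly increasing")
  if (any(snapshot_times < 0 | snapshot_times > t_final))
    stop("`snapshot_times` must lie in [0, t_final]")
  structure(list(d = as.numeric(d), t_final = as.numeric(t_final),
                 seed = as.integer(seed), snapshot_times = snapshot_times),
            class = "simulation_params")
}

#' Simulate the lattice competition model
#'
#' Runs the Gillespie SSA from `grid0` until `t_final` or until the absorbing
#' state (no mutant--wild-type contact) is reached. The state recorded at a
#' snapshot time t is the state after all events with event time <= t
#' (piecewise-constant jump process). The same seed and parameters always give
#' a bit-identical event sequence. Two engines are provided: `"C"` (compiled,
#' incremental contact bookkeeping) and `"R"` (pure R, full contact
#' re-enumeration each step); they consume the RNG stream identically and
#' produce identical trajectories.
#'
#' @param grid0 initial [grid_state()].
#' @param params a [simulation_params()].
#' @param engine `"C"` (default) or `"R"`.
#' @param record_events keep the per-event log (time, site, direction)?
#' @return object of class `competition_trajectory`: list with `params`,
#'   `snapshots` (list of `grid_state`), `observables` (data frame with
#'   `time_days`, `mutant_count`, `boundary_cells`, `boundary_edges`),
#'   `events` (data frame, if recorded), `final_time`, `n_events`.
#' @export
simulate_competition <- function(grid0, params, engine = c("C", "R"),
                                 record_events = FALSE) {
  stopifnot(inherits(grid0, "grid_state"), inherits(params, "simulation_params"))
  engine <- match.arg(engine)
  set.seed(params$seed)
  if (engine == "C") {
    res <- .ssa_run(grid0$occupancy, params$d, params$t_final,
                    params$snapshot_times, boundary_code(grid0), record_events)
  } else {
    res <- ssa_run_r(grid0, params$d, params$t_final, params$snapshot_times,
                     record_events)
  }
  snaps <- lapply(res$snap_occ, function(m)
    grid_state(m, delta = grid0$delta, boundary = grid0$boundary))
  obs <- data.frame(time_days = as.numeric(res$snap_time),
                    mutant_count = as.integer(res$mutant_count),
                    boundary_cells = as.integer(res$boundary_cells),
                    boundary_edges = as.integer(res$boundary_edges))
  structure(list(params = params, snapshots = snaps, observables = obs,
                 events = if (record_events) as.data.frame(res$events) else NULL,
                 final_time = res$final_time, n_events = res$n_events),
            class = "competition_trajectory")
}

# reference engine: full re-enumeration every step; must match .ssa_run exactly
ssa_run_r <- function(grid, d, t_final, snapshot_times, record_events) {
  K <- length(snapshot_times)
  snap_occ <- vector("list", K)
  snap_mut <- snap_bc <- snap_be <- integer(K)
  ev <- list(time_days = numeric(0), i = integer(0), j = integer(0),
             dir = integer(0))
  k <- 1L; t <- 0; n_events <- 0L
  record_upto <- function(horizon) {
    while (k <= K && snapshot_times[k] < horizon) {
      bm <- boundary_metrics(grid)
      snap_occ[[k]] <<- grid$occupancy
      snap_mut[k] <<- sum(grid$occupancy)
      snap_bc[k] <<- bm[["boundary_cells"]]
      snap_be[k] <<- bm[["boundary_edges"]]
      k <<- k + 1L
    }
  }
  repeat {
    contacts <- enumerate_contacts(grid)
    n <- nrow(contacts)
    if (n == 0L || d <= 0) break
    r1 <- runif(1)
    while (r1 <= 0) r1 <- runif(1)
    t_new <- t + log(1 / r1) / (d * n)
    record_upto(t_new)
    if (t_new > t_final) break
    r2 <- runif(1)
    step <- draw_step(contacts, d, r1, r2)
    fired <- contacts[step$fired_index, ]
    grid <- apply_reaction(grid, fired)
    t <- t_new
    n_events <- n_events + 1L
    if (record_events) {
      ev$time_days <- c(ev$time_days, t)
      ev$i <- c(ev$i, fired$m_i)
      ev$j <- c(ev$j, fired$m_j)
      ev$dir <- c(ev$dir, fired$dir)
    }
    if (t >= t_final) break
  }
  record_upto(Inf)
  list(snap_occ = snap_occ, snap_time = snapshot_times, mutant_count = snap_mut,
       boundary_cells = snap_bc, boundary_edges = snap_be, final_time = t,
       n_events = n_events, events = ev)
}

#' @export
print.competition_trajectory <- function(x, ...) {
  cat(sprintf("<competition_trajectory> d = %g/day, t_final = %g days, %d events\n",
              x$params$d, x$params$t_final, x$n_events))
  print(x$observables)
  invisible(x)
}

#' Export trajectory observables as CSV
#'
#' Writes one row per snapshot with columns `time_days`, `mutant_count`,
#' `boundary_cells`, `boundary_edges`, `n_clusters` (4-connected mutant
#' components).
#'
#' @param trajectory a `competition_trajectory`.
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  obs <- trajectory$observables
  obs$n_clusters <- vapply(trajectory$snapshots, function(g) {
    max(0L, max(.label_components(as.integer(g$occupancy),
                                  dim(g$occupancy), 4L)))
  }, integer(1))
  write.csv(obs, path, row.names = FALSE)
  invisible(obs)
}
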