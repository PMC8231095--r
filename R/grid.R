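#' Lattice occupancy grid for the competition model
#'
#' A `grid_state` holds a rectangular lattice in which every site is occupied
#' by exactly one cell, either mutant (1) or wild-type (0). Sites are squares
#' of side `delta` micrometres. Off-grid behaviour is set by `boundary`:
#' `"wildtype_frame"` surrounds the lattice with an infinite sea of wild-type
#' cells (the situation of a mutant patch embedded in normal tissue),
#' `"periodic_x"` wraps columns and closes the row edges (no off-grid
#' neighbour), and `"periodic_xy"` wraps both axes.
#'
#' @param occupancy integer/logical matrix; 1/TRUE = mutant, 0/FALSE = wild-type.
#' @param delta lattice spacing in micrometres (site area is `delta^2`).
#' @param boundary one of `"wildtype_frame"`, `"periodic_x"`, `"periodic_xy"`.
#' @return an object of class `grid_state`.
#' @examples
#' g <- grid_state(matrix(0L, 5, 5), delta = 1)
#' g$occupancy[3, 3] <- 1L
#' @export
grid_state <- function(occupancy,
                       delta = 1,
                       boundary = c("wildtype_frame", "periodic_x", "periodic_xy")) {
  boundary <- match.arg(boundary)
  if (!is.matrix(occupancy)) stop("`occupancy` must be a matrix")
  occ <- occupancy
  storage.mode(occ) <- "integer"
  if (nrow(occ) < 1L || ncol(occ) < 1L) stop("grid dimensions must be >= 1")
  if (anyNA(occ) || !all(occ %in% c(0L, 1L)))
    stop("occupancy values must be 0 (wild-type) or 1 (mutant)")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a single positive number")
  structure(list(occupancy = occ, delta = as.numeric(delta), boundary = boundary),
            class = "grid_state")
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("<grid_state> %d x %d sites, delta = %g um, boundary = %s\n",
              nrow(x$occupancy), ncol(x$occupancy), x$delta, x$boundary))
  cat(sprintf("  mutant sites: %d (%.1f%%)\n", sum(x$occupancy),
              100 * mean(x$occupancy)))
  invisible(x)
}

boundary_code <- function(grid) {
  match(grid$boundary, c("wildtype_frame", "periodic_x", "periodic_xy")) - 1L
}

#' Pixel offsets of a quasi-circular disc patch
#'
#' Returns the `n_pixels` lattice offsets closest to the origin (ties broken
#' deterministically by row then column), i.e. a digital disc with exactly the
#' requested number of sites.
#'
#' @param n_pixels number of sites in the disc (>= 1).
#' @return two-column integer matrix of (row, col) offsets around (0, 0).
#' @keywords internal
disc_offsets <- function(n_pixels) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 1L) stop("disc must contain at least one site")
  r <- ceiling(sqrt(n_pixels / pi)) + 2L
  idx <- expand.grid(row = -r:r, col = -r:r)
  d2 <- idx$row^2 + idx$col^2
  ord <- order(d2, idx$row, idx$col)
  as.matrix(idx[ord[seq_len(n_pixels)], , drop = FALSE])
}

#' Build a grid holding one disc-shaped mutant patch in a wild-type field
#'
#' The patch has exactly `round(area / delta^2)` mutant sites arranged as a
#' digital disc; the grid is the patch bounding box plus a margin of wild-type
#' sites, with a `wildtype_frame` boundary so the patch is effectively embedded
#' in an infinite normal tissue.
#'
#' @param area patch area in square micrometres.
#' @param delta lattice spacing, micrometres.
#' @param margin wild-type margin in sites around the patch bounding box.
#' @return a `grid_state`.
#' @export
disc_patch_grid <- function(area, delta = 1, margin = 1L) {
  n_px <- round(area / delta^2)
  if (n_px < 1) stop("patch area smaller than one lattice site")
  off <- disc_offsets(n_px)
  rr <- off[, 1L] - min(off[, 1L]) + 1L + margin
  cc <- off[, 2L] - min(off[, 2L]) + 1L + margin
  occ <- matrix(0L, max(rr) + margin, max(cc) + margin)
  occ[cbind(rr, cc)] <- 1L
  grid_state(occ, delta = delta, boundary = "wildtype_frame")
}

#' Build a flat mutant--wild-type interface on a periodic strip
#'
#' Lattice of `mutant_rows + wildtype_rows` rows by `width` columns, periodic
#' along the columns and closed along the rows. The lower block of rows is
#' mutant, so exactly `width` mutant cells sit on the interface, each with
#' exactly one wild-type neighbour.
#'
#' @param width number of columns (the periodic axis).
#' @param mutant_rows,wildtype_rows rows in the mutant and wild-type blocks.
#' @param delta lattice spacing, micrometres.
#' @return a `grid_state` with boundary `"periodic_x"`.
#' @export
flat_interface_grid <- function(width = 512L, mutant_rows = 32L,
                                wildtype_rows = 32L, delta = 1) {
  occ <- matrix(0L, mutant_rows + wildtype_rows, width)
  occ[seq_len(mutant_rows) + wildtype_rows, ] <- 1L
  grid_state(occ, delta = delta, boundary = "periodic_x")
}
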