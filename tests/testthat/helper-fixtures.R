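# shared fixtures, all generated in code

# digital disc of radius r (pixels), with a 1-px background margin
disc_mask <- function(r) {
  n <- 2 * r + 3
  m <- matrix(0L, n, n)
  cen <- (n + 1) / 2
  m[(row(m) - cen)^2 + (col(m) - cen)^2 <= r^2] <- 1L
  m
}

# random occupancy grid
random_grid <- function(nr, nc, p_mutant, boundary = "wildtype_frame") {
  grid_state(matrix(rbinom(nr * nc, 1, p_mutant), nr, nc), boundary = boundary)
}

# noiseless samples of a power law on log-spaced areas
power_law_points <- function(a, b, n = 200, range = c(100, 20000)) {
  x <- exp(seq(log(range[1]), log(range[2]), length.out = n))
  data.frame(x = x, y = a * x^b)
}

# two side-by-side rectangular cells with centred nuclei
two_cell_image <- function() {
  cells <- label_image(cbind(matrix(1L, 6, 4), matrix(2L, 6, 4)))
  nuclei <- data.frame(label = 1:2, row_um = c(2.5, 2.5), col_um = c(1.5, 5.5),
                       clone = c(TRUE, FALSE))
  list(cells = cells, nuclei = nuclei)
}
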