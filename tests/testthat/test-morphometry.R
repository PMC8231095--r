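test_that("segmentation respects connectivity, min_area and label permutation", {
  expect_identical(nrow(segment_clusters(matrix(0L, 5, 5))), 0L)
  # diagonal pixels: separate under 4-connectivity, merged under 8
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_identical(nrow(segment_clusters(m, connectivity = 4)), 2L)
  expect_identical(nrow(segment_clusters(m, connectivity = 8)), 1L)
  # min_area drops small components (areas in physical units)
  m2 <- matrix(0L, 10, 10); m2[1:3, 1:3] <- 1L; m2[8, 8] <- 1L
  li <- label_image(m2, c(2, 2))  # pixel area 4 um^2
  recs <- segment_clusters(li, min_area = 5)
  expect_identical(nrow(recs), 1L)
  expect_equal(recs$area_um2, 9 * 4)
  # idempotent and invariant to how the mask encodes foreground
  r1 <- segment_clusters(m2)
  r2 <- segment_clusters((m2 > 0) * 7L)  # any non-zero labelling
  expect_equal(r1$area_um2, r2$area_um2)
})

test_that("density by size normalises counts to tissue area", {
  recs <- data.frame(area_um2 = c(10, 10, 10))
  dist <- density_by_size(recs, tissue_area_mm2 = 1, bin_edges = c(0, 100, Inf))
  expect_equal(dist$density, c(3, 0))
  expect_equal(sum(dist$density), nrow(recs) / 1)
  # total density is invariant to the binning
  dist2 <- density_by_size(recs, 1, bin_edges = c(0, 5, 20, Inf))
  expect_equal(sum(dist2$density), sum(dist$density))
  # the 2,000 um^2 small-cluster threshold is a default bin edge
  expect_true(2000 %in% default_bin_edges())
  expect_error(density_by_size(recs, 0), "> 0")
  empty <- density_by_size(recs[0, , drop = FALSE], 2)
  expect_true(all(empty$density == 0))
})

test_that("circularity follows the closed forms and approaches 1 for discs", {
  # n x n square with naive edge-count perimeter 4n: score is exactly pi/4
  sq <- matrix(1L, 16, 16)
  expect_equal(as.numeric(circularity(sq, method = "edge")), pi / 4)
  # digital discs under the Crofton perimeter approach the continuum value 1
  scores <- vapply(c(10, 50, 200), function(r)
    as.numeric(circularity(disc_mask(r))), numeric(1))
  expect_gt(scores[2], 0.95)
  expect_true(all(diff(scores) > 0))       # monotone approach
  expect_true(all(abs(scores - 1) < 0.1))
  # clamping: never above 1, raw value preserved
  c1 <- circularity(disc_mask(30))
  expect_lte(as.numeric(c1), 1)
  expect_gt(attr(c1, "raw"), 0)
  expect_error(circularity(array(1L, c(2, 2, 2))), "3D")
  expect_error(circularity(matrix(1L, 3, 3), spacing = c(1, 2)), "isotropic")
})

test_that("sphericity index separates smooth convex from lobed boundaries", {
  expect_gt(sphericity_index(disc_mask(20)), 0.95)
  expect_equal(sphericity_index(matrix(c(1L), 1, 1)), 1)  # single pixel
  plus <- matrix(0L, 31, 31)
  plus[14:18, 4:28] <- 1L; plus[4:28, 14:18] <- 1L
  expect_lt(sphericity_index(plus), 0.9)
  # invariance under translation and 90-degree rotation
  pad <- matrix(0L, 41, 41); pad[6:36, 6:36] <- plus
  expect_equal(sphericity_index(pad), sphericity_index(plus), tolerance = 1e-9)
  rot <- t(plus[nrow(plus):1, ])
  expect_equal(sphericity_index(rot), sphericity_index(plus), tolerance = 1e-9)
})

test_that("shape metrics are translation and rotation invariant in physical units", {
  blob <- matrix(0L, 30, 40)
  blob[5:20, 8:30] <- 1L; blob[15:25, 20:35] <- 1L
  metrics <- function(m) c(perimeter2d(m), as.numeric(circularity(m)),
                           sphericity_index(m), sum(m))
  base <- metrics(blob)
  shifted <- matrix(0L, 50, 60); shifted[11:40, 15:54] <- blob
  expect_equal(metrics(shifted), base, tolerance = 1e-9)
  rot <- t(blob[nrow(blob):1, ])
  expect_equal(metrics(rot), base, tolerance = 1e-9)
})

test_that("label area fraction and 3D cell volume follow their definitions", {
  tissue <- matrix(1L, 10, 10)
  expect_equal(label_area_fraction(tissue, tissue), 100)
  expect_equal(label_area_fraction(matrix(0L, 10, 10), tissue), 0)
  lab <- matrix(0L, 10, 10); lab[1:2, 1:5] <- 1L
  expect_equal(label_area_fraction(lab, tissue), 10)
  expect_error(label_area_fraction(lab, matrix(0L, 10, 10)), "empty tissue")
  # volume: voxel count x voxel volume, additive over labels
  arr <- array(0L, c(5, 5, 4))
  arr[1:2, 1:5, 1] <- 1L   # 10 voxels
  arr[3, 3, 2:4] <- 2L     # 3 voxels
  li <- label_image(arr, c(1, 1, 2))
  expect_equal(cell_volume(li, 1), 20)
  expect_equal(cell_volume(li, 2), 6)  # 3 voxels x 2 um^3
  expect_error(cell_volume(li, 9), "not present")
})
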