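test_that("mosaics hit the target label fraction and are fully reproducible", {
  mo <- generate_mosaic(c(512, 512), target_label_fraction = 20, seed = 42)
  expect_gte(mo$truth$label_fraction, 19)
  expect_lte(mo$truth$label_fraction, 21)
  # truth is consistent with the emitted mask
  expect_equal(mo$truth$label_fraction,
               label_area_fraction(mo$mask$data > 0,
                                   matrix(1L, 512, 512)))
  expect_identical(max(mo$mask$data), nrow(mo$truth$clusters))
  # byte-identical under the same seed
  mo2 <- generate_mosaic(c(512, 512), target_label_fraction = 20, seed = 42)
  expect_identical(mo$mask$data, mo2$mask$data)
  expect_identical(mo$truth$clusters, mo2$truth$clusters)
  expect_error(generate_mosaic(c(0, 10)), "positive area")
})

test_that("realised cluster areas follow the target truncated power law", {
  set.seed(7)
  x <- sample_cluster_areas(2000)
  ks <- suppressWarnings(ks.test(x, power_law_cdf))
  expect_lt(unname(ks$statistic), 0.05)
  # exponent recovered by histogram regression over pooled mosaics
  set.seed(8)
  areas <- unlist(lapply(1:20, function(k)
    generate_mosaic(c(512, 512), seed = 1000 + k)$truth$clusters$area_um2))
  edges <- exp(seq(log(25), log(20000), length.out = 13))
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  dens <- as.integer(table(cut(areas, edges))) / diff(edges)
  pts <- data.frame(x = mids, y = dens)[dens > 0, ]
  f <- fit_power_law(pts, log_space = TRUE)
  expect_lt(abs(f$b - (-1.067)), 0.15)
})

test_that("cell packings partition the tissue and scale IND with compaction", {
  mo <- generate_mosaic(c(256, 256), seed = 5, area_range = c(200, 3000))
  pk1 <- generate_cell_packing(mo, mean_cell_diameter = 8, compaction = 1,
                               seed = 9)
  # every pixel belongs to exactly one cell
  expect_true(all(pk1$cells$data > 0L))
  # symmetric construction: clone and normal IND agree within 5%
  g1 <- build_cell_graph(pk1$cells, pk1$nuclei)
  ind_in1 <- internuclear_distances(g1, pk1$nuclei$label[pk1$nuclei$clone])
  ind_out1 <- internuclear_distances(g1, pk1$nuclei$label[!pk1$nuclei$clone])
  expect_lt(abs(mean(ind_in1) / mean(ind_out1) - 1), 0.05)
  # compaction c = 0.8 shrinks within-clone IND by ~c
  pk08 <- generate_cell_packing(mo, mean_cell_diameter = 8, compaction = 0.8,
                                seed = 9)
  g08 <- build_cell_graph(pk08$cells, pk08$nuclei)
  ind_in <- internuclear_distances(g08, pk08$nuclei$label[pk08$nuclei$clone])
  ind_out <- internuclear_distances(g08, pk08$nuclei$label[!pk08$nuclei$clone])
  expect_lt(abs(mean(ind_in) / mean(ind_out) - 0.8), 0.08)
  expect_error(generate_cell_packing(mo, mean_cell_diameter = 1.5),
               "at least 2 pixels")
})

test_that("rendered channels encode the interface attenuation exactly when noiseless", {
  mo <- generate_mosaic(c(192, 192), seed = 11, area_range = c(200, 2000))
  pk <- generate_cell_packing(mo, mean_cell_diameter = 8, seed = 3)
  # f = 1, no noise: all interface pixels share one value
  ch1 <- render_channels(pk, base_intensity = 100, clone_normal_factor = 1,
                         gaussian_noise_sd = 0, seed = 2)
  vals <- ch1$membrane[ch1$graph$pixel_class > 0L]
  expect_identical(unique(vals), 100)
  # f = 0.5, no noise: clone-normal mean is exactly half the normal-normal mean
  ch <- render_channels(pk, base_intensity = 100, clone_normal_factor = 0.5,
                        gaussian_noise_sd = 0, seed = 2)
  nn <- interface_intensity(ch$membrane, ch$graph, "normal-normal")
  cn <- interface_intensity(ch$membrane, ch$graph, "clone-normal")
  expect_equal(mean(cn$mean_intensity, na.rm = TRUE) /
                 mean(nn$mean_intensity, na.rm = TRUE), 0.5)
  expect_error(render_channels(pk, clone_normal_factor = 3), "0, 2")
})

test_that("time series are inert at d = 0 and mutant area never grows", {
  mo <- generate_mosaic(c(192, 192), seed = 21, area_range = c(100, 2000))
  ts0 <- generate_time_series(mo, d_true = 0, snapshot_days = c(0, 7, 35),
                              seed = 4)
  expect_true(all(ts0$areas[, "day7", 1] == ts0$areas[, "day0", 1]))
  expect_true(all(ts0$areas[, "day35", 1] == ts0$areas[, "day0", 1]))
  ts <- generate_time_series(mo, d_true = 0.15, snapshot_days = c(0, 7, 35),
                             n_replicates = 2, seed = 4)
  for (r in 1:2) {
    expect_true(all(diff(t(ts$areas[, , r])) <= 0))  # per-cluster decline
  }
  # day-0 table equals the mosaic's own density table
  d0 <- time_series_distribution(ts, 0)
  ref <- density_by_size(mo$truth$clusters, mo$truth$tissue_area_mm2)
  expect_equal(d0$density, ref$density)
  # reproducible under the same seed
  ts2 <- generate_time_series(mo, d_true = 0.15, snapshot_days = c(0, 7, 35),
                              n_replicates = 2, seed = 4)
  expect_identical(ts$areas, ts2$areas)
})
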