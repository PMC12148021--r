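test_that("embryo generation is deterministic and respects its geometry", {
  emb1 <- small_embryo(seed = 11L)
  emb2 <- small_embryo(seed = 11L)
  expect_identical(emb1$membrane$data, emb2$membrane$data)
  expect_identical(emb1$labels$labels, emb2$labels$labels)
  # all cell labels live inside the ellipsoid mask
  expect_true(all(emb1$labels$labels[!emb1$mask] == 0L))
  expect_true(all(emb1$labels$labels[emb1$mask] > 0L))
  expect_identical(max(emb1$labels$labels), 8L)
})

test_that("a single-cell embryo has its membrane on the ellipsoid shell", {
  # near-delta PSF so the shell stays sharp: membrane bright exactly there
  emb <- generate_embryo(embryo_geometry(volume_shape = c(16, 32, 32),
                                         voxel_size_um = c(0.3, 0.15, 0.15),
                                         n_cells = 1L, seed = 2L),
                         background_level = 0,
                         psf_sigma_um = c(0.06, 0.03, 0.03))
  expect_identical(max(emb$labels$labels), 1L)
  b <- boundary_mask(emb$labels)
  # boundary voxels coincide with the mask's surface shell: all are in-mask
  # and touch the outside
  expect_true(all(emb$mask[b]))
  interior_deep <- emb$labels$labels > 0 & !b
  expect_gt(min(emb$membrane$data[b]), 100)
  expect_lt(median(emb$membrane$data[interior_deep]), 1)
})

test_that("boundary voxels are brighter than background in the membrane channel", {
  emb <- small_embryo(seed = 5L)
  b <- boundary_mask(emb$labels)
  bg_med <- median(emb$membrane$data[!b])
  expect_true(all(emb$membrane$data[b] > bg_med))
})

test_that("volumes too small for the requested cells are rejected", {
  expect_error(generate_embryo(embryo_geometry(volume_shape = c(4, 6, 6),
                                               n_cells = 50L)),
               "too small")
})

test_that("spot placement honours the membrane-proximal band construction", {
  emb <- small_embryo(seed = 7L)
  all_in <- place_and_render_spots(
    emb$labels, spot_params(n_spots = 50L, p_membrane = 1, seed = 1L))
  expect_true(all(all_in$truth$membrane_distance_um <= 0.35))
  all_out <- place_and_render_spots(
    emb$labels, spot_params(n_spots = 50L, p_membrane = 0, seed = 1L))
  expect_true(all(all_out$truth$membrane_distance_um > 0.35))
  # conservation: one truth row per requested spot, rendering deterministic
  expect_identical(nrow(all_in$truth), 50L)
  again <- place_and_render_spots(
    emb$labels, spot_params(n_spots = 50L, p_membrane = 1, seed = 1L))
  expect_identical(again$spots$data, all_in$spots$data)
})

test_that("realized proximal fraction converges to p_membrane", {
  # binomial: at n = 2000, a +-0.03 band is ~2.7 sd around p = 0.5
  emb <- small_embryo(shape = c(28, 88, 88), n_cells = 10L, seed = 13L)
  scene <- place_and_render_spots(
    emb$labels, spot_params(n_spots = 2000L, p_membrane = 0.5, seed = 17L))
  frac <- mean(scene$truth$membrane_distance_um <= 0.35)
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("minimum spot separation is enforced when requested", {
  emb <- small_embryo(seed = 7L)
  scene <- place_and_render_spots(
    emb$labels, spot_params(n_spots = 60L, p_membrane = 0.3,
                            min_separation_um = 1.0, seed = 3L))
  pos <- as.matrix(scene$truth[, c("z_um", "y_um", "x_um")])
  dmin <- min(dist(pos))
  expect_gte(dmin, 1.0)
})

test_that("coloc scenes: identical channels at full overlap and efficiency", {
  emb <- small_embryo(seed = 9L)
  p <- coloc_params(n_mrna = 80L, true_overlap_fraction = 1,
                    detection_efficiency = c(1, 1),
                    max_pairing_offset_um = 0, seed = 2L)
  pair <- generate_coloc_pair(emb$labels, p)
  expect_identical(nrow(pair$table1), 80L)
  expect_equal(pair$table1$x_um, pair$table2$x_um)
  expect_equal(pair$table1$z_um, pair$table2$z_um)
  # no pairings when the true overlap is zero
  p0 <- coloc_params(n_mrna = 80L, true_overlap_fraction = 0, seed = 2L)
  expect_identical(nrow(generate_coloc_pair(emb$labels, p0)$truth$pairings), 0L)
})

test_that("coloc detection-efficiency thinning matches its binomial law", {
  emb <- small_embryo(seed = 9L)
  p <- coloc_params(n_mrna = 1000L, true_overlap_fraction = 1,
                    detection_efficiency = c(1, 0.62),
                    max_pairing_offset_um = 0.1, seed = 8L)
  pair <- generate_coloc_pair(emb$labels, p)
  # channel-2 renders ~62% of spots (binomial, ~3 sd band)
  expect_lt(abs(nrow(pair$table2) / 1000 - 0.62), 0.05)
  # conservation: rendered tables match the ground-truth rendering flags
  expect_identical(nrow(pair$table1), sum(pair$truth$rendered1))
  expect_identical(nrow(pair$table2), sum(pair$truth$rendered2))
})

test_that("FRAP simulation satisfies its closed-form ground truth", {
  p <- frap_sim_params(mobile_fraction = 0.6, half_time_s = 120)
  sim <- simulate_frap(p)
  i <- which(sim$trace$time_s == 120)
  expect_equal(sim$truth$recovery_true[i], 0.6 * (1 - exp(-log(2))))
  expect_equal(sim$truth$recovery_true[i], 0.30)
  # closed form at every frame
  tt <- sim$trace$time_s
  post <- tt >= 0
  expect_equal(sim$truth$recovery_true[post],
               0.6 * (1 - exp(-tt[post] * log(2) / 120)))
})

test_that("immobile FRAP trace is flat after acquisition-bleach correction", {
  p <- frap_sim_params(mobile_fraction = 0, acquisition_bleach_rate = 0.99)
  sim <- simulate_frap(p)
  tr <- correct_trace(sim$trace)
  post <- sim$trace$time_s >= 0
  expect_lt(diff(range(tr$corrected[post])), 1e-12)
})

test_that("without corruption the raw trace is the scaled truth", {
  p <- frap_sim_params(acquisition_bleach_rate = 1, background_level = 0,
                       noise_sd = 0, signal_level = 1000, bleach_depth = 0.7)
  sim <- simulate_frap(p)
  post <- sim$trace$time_s >= 0
  expected <- 1000 * (1 - 0.7) + 1000 * 0.7 * sim$truth$recovery_true[post]
  expect_equal(sim$trace$bleached[post], expected)
})

test_that("line-scan fixture encodes its construction ratio", {
  ls <- generate_linescan_image(300, 100, 50)
  img <- ls$image$data
  expect_equal(max(img), 300)
  expect_equal(img[1, ls$layout$background_cols[1]], 50)
  expect_equal(img[1, ls$layout$cyto_cols[1]], 100)
  expect_error(generate_linescan_image(100, 200, 50), "apical_value")
})
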