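test_that("denoising is the identity at sigma 0 and conserves intensity", {
  st <- image_stack(array(runif(6 * 20 * 20), c(6, 20, 20)), c(0.4, 0.13, 0.13))
  expect_identical(denoise_spot_channel(st, 0)$data, st$data)
  sm <- denoise_spot_channel(st, c(0.4, 0.2, 0.2))
  expect_equal(sum(sm$data), sum(st$data), tolerance = 1e-10)
  expect_error(denoise_spot_channel(st, -1), "nonnegative")
})

test_that("denoising suppresses a hot pixel by the kernel mass", {
  a <- array(0, c(9, 21, 21))
  a[5, 11, 11] <- 1000
  st <- image_stack(a, c(0.2, 0.1, 0.1))
  sm <- denoise_spot_channel(st, 0.4) # sigma of 2-4 voxels per axis
  expect_lt(max(sm$data), 100) # peak reduced by > 10x
})

test_that("membrane enhancement leaves constants alone and peaks on edges", {
  cfg <- run_config()
  flat <- image_stack(array(7, c(6, 16, 16)), c(0.3, 0.15, 0.15))
  enh <- enhance_membrane(flat, cfg)
  expect_equal(enh$data, flat$data, tolerance = 1e-12)
  # ideal step along x: the edge response is maximal on the step plane
  a <- array(0, c(6, 16, 16))
  a[, , 9:16] <- 100
  st <- image_stack(a, c(0.3, 0.15, 0.15))
  enh <- enhance_membrane(st, cfg)
  edge_term <- enh$data - (st$data + cfg$seg_sharpen_amount *
                             (st$data - memloc:::gaussian_smooth(
                               st$data, st$voxel_size,
                               cfg$seg_sharpen_sigma_um)))
  profile <- apply(edge_term, 3, mean)
  expect_true(which.max(profile) %in% 8:9)
})

test_that("membrane enhancement lights up the true boundary voxels", {
  emb <- small_embryo(seed = 5L)
  enh <- enhance_membrane(emb$membrane, run_config())
  b <- boundary_mask(emb$labels)
  inside_bg <- emb$labels$labels > 0 & !b
  expect_gt(mean(enh$data[b]), 2 * mean(enh$data[inside_bg]))
})

test_that("watershed recovers the cells of a synthetic embryo", {
  emb <- small_embryo(shape = c(32, 96, 96), n_cells = 12L, seed = 3L)
  cfg <- run_config()
  seg <- segment_cells(enhance_membrane(emb$membrane, cfg), emb$mask, cfg)
  expect_identical(max(seg$labels), 12L)
  expect_gt(label_agreement(emb$labels$labels, seg$labels), 0.95)
  expect_error(segment_cells(enhance_membrane(emb$membrane, cfg),
                             array(FALSE, dim(emb$mask)), cfg),
               "empty")
})

test_that("a single-cell embryo segments into one label", {
  emb <- generate_embryo(embryo_geometry(volume_shape = c(16, 40, 40),
                                         voxel_size_um = c(0.3, 0.15, 0.15),
                                         n_cells = 1L, seed = 2L))
  cfg <- run_config()
  seg <- segment_cells(enhance_membrane(emb$membrane, cfg), emb$mask, cfg)
  expect_identical(max(seg$labels), 1L)
})

test_that("two blocks separated by a bright plane split into two labels", {
  a <- array(0, c(16, 12, 12))
  a[8:9, , ] <- 1000
  st <- image_stack(a, c(0.2, 0.2, 0.2))
  mask <- array(TRUE, dim(a))
  seg <- segment_cells(st, mask, run_config(seg_smooth_sigma_um = 0.2,
                                            seg_h_min = 100))
  expect_identical(max(seg$labels), 2L)
  expect_true(length(unique(seg$labels[c(2, 15), 6, 6])) == 2L)
})

test_that("embryo mask recovers the ellipsoid", {
  emb <- generate_embryo(embryo_geometry(volume_shape = c(48, 96, 96),
                                         voxel_size_um = c(0.25, 0.15, 0.15),
                                         n_cells = 12L, seed = 9L))
  msk <- embryo_mask(emb$membrane)
  dice <- 2 * sum(msk & emb$mask) / (sum(msk) + sum(emb$mask))
  expect_gte(dice, 0.95)
})

test_that("exclusion masks clip to the volume and drop enclosed spots", {
  emb <- small_embryo(seed = 5L)
  expect_false(any(exclusion_mask(NULL, emb$membrane)))
  rois <- data.frame(zmin_um = 0, zmax_um = 2, ymin_um = 0, ymax_um = 2,
                     xmin_um = 0, xmax_um = 2)
  ex <- exclusion_mask(rois, emb$membrane)
  expect_true(ex[1, 1, 1])
  expect_false(ex[dim(ex)[1], 1, 1])
  big <- data.frame(zmin_um = 0, zmax_um = 1e4, ymin_um = 0, ymax_um = 1e4,
                    xmin_um = 0, xmax_um = 1e4)
  expect_warning(ex2 <- exclusion_mask(big, emb$membrane), "clip")
  expect_true(all(ex2))
  # spots under an exclusion ROI vanish from the detection table
  scene <- place_and_render_spots(emb$labels,
                                  spot_params(n_spots = 40L, seed = 2L))
  cfg <- scene_config()
  with_ex <- detect_spots(scene$spots, cfg, exclude = array(TRUE, dim(ex)))
  expect_identical(nrow(with_ex), 0L)
})

test_that("distance maps follow grid arithmetic on toy volumes", {
  # membrane along the x = 1 column of a single plane, 0.1 um voxels
  lab <- array(0L, c(1, 5, 5))
  lab[1, , ] <- 1L
  lv <- label_volume(lab, c(1, 0.1, 0.1))
  dm <- distance_to_membrane(lv)
  # every voxel of a 1-z-plane cell is boundary (faces outside in z)
  expect_true(all(dm$dist == 0))
  # anisotropic: boundary one z-plane away costs the z spacing
  lab2 <- array(1L, c(4, 4, 4))
  lv2 <- label_volume(lab2, c(0.4, 0.1, 0.1))
  dm2 <- distance_to_membrane(lv2)
  expect_equal(dm2$dist[2, 2, 2], 0.1) # nearest face is in-plane
  inner <- dm2$dist[2:3, 2:3, 2:3]
  expect_equal(as.vector(inner), rep(0.1, 8))
  expect_error(distance_to_membrane(label_volume(array(0L, c(2, 2, 2)),
                                                 c(1, 1, 1))),
               "boundary")
})

test_that("the distance transform equals brute force on random volumes", {
  set.seed(42)
  for (k in 1:10) {
    d <- c(sample(3:8, 1), sample(3:10, 1), sample(3:10, 1))
    spacing <- c(runif(1, 0.2, 0.5), runif(1, 0.05, 0.2), runif(1, 0.05, 0.2))
    feature <- array(runif(prod(d)) < 0.08, d)
    if (!any(feature)) feature[1] <- TRUE
    got <- array(sqrt(memloc:::cpp_edt_sq(as.logical(feature), d, spacing)), d)
    expect_equal(got, brute_force_distance(feature, spacing), tolerance = 1e-12)
  }
})

test_that("outputs inherit the input voxel calibration", {
  emb <- small_embryo(seed = 5L)
  cfg <- run_config()
  enh <- enhance_membrane(emb$membrane, cfg)
  seg <- segment_cells(enh, emb$mask, cfg)
  dm <- distance_to_membrane(seg)
  expect_identical(voxel_size(enh), voxel_size(emb$membrane))
  expect_identical(voxel_size(seg), voxel_size(emb$membrane))
  expect_identical(voxel_size(dm), voxel_size(emb$membrane))
})
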