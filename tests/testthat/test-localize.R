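test_that("spot distances sample the map correctly on toy grids", {
  # plane with membrane everywhere at z boundaries: distances from dmap
  lab <- array(1L, c(1, 5, 5))
  lab[1, , 2:5] <- 2L # boundary between x columns 1 and 2
  lv <- label_volume(lab, c(1, 0.1, 0.1))
  dm <- distance_to_membrane(lv)
  # a spot exactly on a boundary voxel centre has distance 0
  df <- data.frame(id = 1L, channel = "a", z_um = NA_real_, y_um = 0.2,
                   x_um = 0.0, peak_intensity = 1, integrated_intensity = 1,
                   category = "unassigned", membrane_distance_um = NA_real_)
  # 2D map from 3D single-plane volume: drop z
  dm2 <- distance_map(dm$dist[1, , ], c(0.1, 0.1))
  got <- spot_membrane_distances(spot_table(df), dm2)
  expect_equal(got$membrane_distance_um, 0)
  out <- df
  out$x_um <- 2 # outside the 0.4 um extent
  expect_error(spot_membrane_distances(spot_table(out), dm2), "outside")
})

test_that("interpolated distances agree with brute force at spot centres", {
  set.seed(7)
  lab <- array(0L, c(8, 12, 12))
  lab[2:7, 2:11, 2:11] <- 1L
  lab[4:7, 5:11, 2:11] <- 2L
  vs <- c(0.3, 0.12, 0.12)
  lv <- label_volume(lab, vs)
  dm <- distance_to_membrane(lv)
  b <- boundary_mask(lv)
  bf <- brute_force_distance(b, vs)
  pos <- cbind(runif(100, 0, 7 * 0.3), runif(100, 0, 1.32), runif(100, 0, 1.32))
  got <- memloc:::interp_map(dm, pos)
  want <- memloc:::interp_map(distance_map(bf, vs), pos)
  expect_equal(got, want, tolerance = 1e-12)
  # and interpolation error vs exact point-to-boundary distance is bounded
  # by half a voxel diagonal
  bpos <- sweep(arrayInd(which(b), dim(b)) - 1, 2, vs, `*`)
  exact <- apply(pos, 1, function(p) {
    sqrt(min((bpos[, 1] - p[1])^2 + (bpos[, 2] - p[2])^2 + (bpos[, 3] - p[3])^2))
  })
  expect_lt(max(abs(got - exact)), sqrt(sum(vs^2)) / 2 + 1e-9)
})

test_that("proximity fraction applies the inclusive 0.35 um cutoff", {
  df <- data.frame(id = 1:5, channel = "gfp", z_um = 1, y_um = 1, x_um = 1:5,
                   peak_intensity = 1, integrated_intensity = 1,
                   category = "unassigned",
                   membrane_distance_um = c(0.10, 0.30, 0.35, 0.40, 1.20))
  res <- proximity_fraction(spot_table(df), 0.35)
  expect_equal(res$fraction_within, 0.60)
  expect_identical(res$n_within, 3L)
  far <- df
  far$membrane_distance_um <- far$membrane_distance_um + 10
  expect_equal(proximity_fraction(spot_table(far), 0.35)$fraction_within, 0)
  expect_error(proximity_fraction(spot_table(), 0.35), "no spots")
  # monotone non-decreasing in the cutoff
  fr <- vapply(seq(0, 1.5, by = 0.05), function(cc) {
    proximity_fraction(spot_table(df), cc)$fraction_within
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("the z-flip is an involution that conserves intensity", {
  st <- image_stack(array(rnorm(5 * 8 * 8), c(5, 8, 8)), c(0.4, 0.13, 0.13))
  flip <- zflip_null(st)
  expect_equal(sum(flip$data), sum(st$data))
  expect_identical(zflip_null(flip)$data, st$data)
  one <- image_stack(array(0, c(5, 3, 3)), c(0.4, 0.13, 0.13))
  one$data[1, 2, 2] <- 9
  expect_equal(zflip_null(one)$data[5, 2, 2], 9)
})

test_that("category rules resolve nuclear pore before membrane before cytosol", {
  lab <- array(1L, c(6, 20, 20))
  vs <- c(0.3, 0.1, 0.1)
  lv <- label_volume(lab, vs)
  dm_mem <- distance_to_membrane(lv)
  # synthetic nuclear surface: a small block in the middle
  nuc <- array(0L, dim(lab))
  nuc[3:4, 9:12, 9:12] <- 1L
  dm_nuc <- distance_to_membrane(label_volume(nuc, vs))
  mk <- function(z, y, x) {
    spot_table(data.frame(id = 1L, channel = "a", z_um = z, y_um = y, x_um = x,
                          peak_intensity = 1, integrated_intensity = 1,
                          category = "unassigned",
                          membrane_distance_um = NA_real_))
  }
  near_nuc <- categorize_spots(mk(0.9, 1.0, 1.0), dm_mem, dm_nuc, 0.35)
  expect_identical(near_nuc$spots$category, "nuclear_pore")
  far_both <- categorize_spots(mk(0.9, 0.5, 0.5), dm_mem, dm_nuc, 0.35)
  expect_identical(far_both$spots$category, "cytosol")
  on_memb <- categorize_spots(mk(0.0, 0.5, 0.5), dm_mem, dm_nuc, 0.35)
  expect_identical(on_memb$spots$category, "membrane")
  # without a nuclear map only membrane/cytosol are assigned
  no_nuc <- categorize_spots(mk(0.9, 1.0, 1.0), dm_mem, NULL, 0.35)
  expect_true(no_nuc$spots$category %in% c("membrane", "cytosol"))
  expect_equal(sum(near_nuc$fractions), 1)
})

test_that("known placement classes are recovered from a synthetic scene", {
  emb <- small_embryo(shape = c(28, 84, 84), n_cells = 6L, seed = 15L)
  nuc <- generate_nuclei(emb$labels, radius_um = 1.0)
  truth <- place_categorized_spots(emb$labels, nuc,
                                   class_probs = c(0.8, 0.1, 0.1),
                                   n_spots = 600L, cutoff_um = 0.35,
                                   seed = 5L)
  tb <- truth_to_spot_table(truth)
  got <- categorize_spots(tb, distance_to_membrane(emb$labels),
                          nuc$dmap, 0.35)
  expect_lt(abs(got$fractions[["nuclear_pore"]] - 0.8), 0.05)
  # rule-level agreement with the generated classes is exact by construction
  expect_identical(unname(got$spots$category), truth$class)
})

test_that("re-localization summary applies the >7-spot rule and averages", {
  res <- list(
    c(nuclear_pore = 7, membrane = 2, cytosol = 1),   # 10 spots, 70%
    c(nuclear_pore = 4, membrane = 2, cytosol = 1),   # 7 spots: excluded
    c(nuclear_pore = 6, membrane = 2, cytosol = 2)    # 10 spots, 60%
  )
  rep <- relocalization_report(res, min_spots = 7L)
  expect_equal(rep$per_embryo$nuclear_pore[1], 70)
  expect_identical(rep$excluded, 2L)
  expect_equal(rep$summary$mean_pct[rep$summary$category == "nuclear_pore"],
               mean(c(70, 60)))
})
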