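mk_table <- function(pos, channel = "a") {
  spot_table(data.frame(
    id = seq_len(nrow(pos)), channel = channel,
    z_um = if (ncol(pos) == 3) pos[, 1] else NA_real_,
    y_um = pos[, ncol(pos) - 1], x_um = pos[, ncol(pos)],
    peak_intensity = 1, integrated_intensity = 1,
    category = "unassigned", membrane_distance_um = NA_real_
  ))
}

test_that("identical tables match perfectly and disjoint ones not at all", {
  set.seed(1)
  pos <- cbind(runif(30, 0, 10), runif(30, 0, 10), runif(30, 0, 10))
  m <- match_spots(mk_table(pos), mk_table(pos, "b"), 0.5)
  expect_equal(m$overlap_fraction_a, 1)
  expect_equal(m$overlap_fraction_b, 1)
  expect_true(all(m$pairs$offset_um == 0))
  far <- pos
  far[, 3] <- far[, 3] + 100
  m0 <- match_spots(mk_table(pos), mk_table(far, "b"), 0.5)
  expect_identical(m0$n_matched, 0L)
  expect_error(match_spots(mk_table(pos), mk_table(pos), -1), "nonnegative")
})

test_that("matching is one-to-one, bounded by the radius, and symmetric", {
  set.seed(2)
  pa <- cbind(runif(40, 0, 8), runif(40, 0, 8), runif(40, 0, 8))
  pb <- pa[1:25, ] + matrix(rnorm(75, 0, 0.05), 25, 3)
  ta <- mk_table(pa)
  tb <- mk_table(pb, "b")
  m <- match_spots(ta, tb, 0.3)
  expect_false(anyDuplicated(m$pairs$id_a) > 0)
  expect_false(anyDuplicated(m$pairs$id_b) > 0)
  expect_true(all(m$pairs$offset_um <= 0.3))
  expect_lte(m$n_matched, min(m$n_a, m$n_b))
  ms <- match_spots(tb, ta, 0.3)
  expect_identical(ms$n_matched, m$n_matched)
  expect_equal(ms$overlap_fraction_a, m$overlap_fraction_b)
})

test_that("matched count is monotone in the radius", {
  set.seed(3)
  pa <- cbind(runif(50, 0, 6), runif(50, 0, 6), runif(50, 0, 6))
  pb <- cbind(runif(50, 0, 6), runif(50, 0, 6), runif(50, 0, 6))
  counts <- vapply(c(0.1, 0.3, 0.6, 1, 2), function(r) {
    match_spots(mk_table(pa), mk_table(pb, "b"), r)$n_matched
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("greedy mutual-NN matching tracks the optimal assignment", {
  # well-separated unique pairs: greedy equals the maximum matching exactly
  set.seed(4)
  base <- cbind(runif(20, 0, 50), runif(20, 0, 50), runif(20, 0, 50))
  pb <- base + matrix(rnorm(60, 0, 0.02), 20, 3)
  m <- match_spots(mk_table(base), mk_table(pb, "b"), 0.2)
  expect_identical(m$n_matched, max_matching_count(base, pb, 0.2))
  expect_identical(m$n_matched, 20L)
  # dense cluttered case: within 2% of the maximum-cardinality oracle
  for (k in 1:5) {
    pa <- cbind(runif(40, 0, 4), runif(40, 0, 4), runif(40, 0, 4))
    pc <- cbind(runif(40, 0, 4), runif(40, 0, 4), runif(40, 0, 4))
    m2 <- match_spots(mk_table(pa), mk_table(pc, "b"), 0.8)
    opt <- max_matching_count(pa, pc, 0.8)
    expect_gte(m2$n_matched, ceiling(0.98 * opt) - 1L)
  }
})

test_that("recovered overlap matches the generator's true fraction", {
  emb <- small_embryo(seed = 9L)
  p <- coloc_params(n_mrna = 1000L, true_overlap_fraction = 0.6,
                    detection_efficiency = c(1, 1),
                    max_pairing_offset_um = 0.1, seed = 5L)
  pair <- generate_coloc_pair(emb$labels, p)
  m <- match_spots(pair$table1, pair$table2, 0.3)
  # channel 1 holds only partnered spots; its fraction of channel 2 is p
  expect_lt(abs(m$overlap_fraction_b - 0.6), 0.04)
})

test_that("translation overlap gates, includes and reports the fraction", {
  set.seed(6)
  pos <- cbind(runif(10, 0, 10), runif(10, 0, 10), runif(10, 0, 10))
  tr <- mk_table(pos)
  tr$integrated_intensity <- rep(30000, 10)
  mr <- mk_table(pos[1:6, , drop = FALSE], "mrna")
  cfg <- run_config(match_radius_um = 0.3)
  res <- translation_overlap(tr, mr, cfg)
  expect_true(res$included)
  expect_equal(res$overlap_fraction, 0.6)
  # zero mRNA spots: 0% overlap
  res0 <- translation_overlap(tr, spot_table(), cfg)
  expect_equal(res0$overlap_fraction, 0)
  # embryos at the >3 rule boundary are excluded
  tr3 <- mk_table(pos[1:3, , drop = FALSE])
  tr3$integrated_intensity <- rep(30000, 3)
  res3 <- translation_overlap(tr3, mr, cfg)
  expect_false(res3$included)
  expect_true(is.na(res3$overlap_fraction))
  # spots below the 25000 gate never count as translation spots
  dim_tab <- tr
  dim_tab$integrated_intensity <- rep(100, 10)
  expect_false(translation_overlap(dim_tab, mr, cfg)$included)
})

test_that("probe efficiencies follow the per-channel division", {
  set.seed(7)
  pos <- cbind(runif(100, 0, 30), runif(100, 0, 30), runif(100, 0, 30))
  t1 <- mk_table(pos)
  t1$integrated_intensity <- rep(60000, 100)
  keep2 <- 1:80
  t2 <- mk_table(pos[keep2, ] + matrix(rnorm(240, 0, 0.02), 80, 3), "b")
  t2$integrated_intensity <- rep(60000, 80)
  # jittered positions are unique and well separated; 60 of channel 2 moved
  # out of reach so that matched = 60
  t2$x_um[61:80] <- t2$x_um[61:80] + 50
  eff <- probe_efficiency(t1, t2, run_config(match_radius_um = 0.3))
  expect_equal(unname(eff$efficiency), c(60 / 100, 60 / 80))
  # identical channels: both efficiencies 1
  eff1 <- probe_efficiency(t1, t1, run_config(match_radius_um = 0.3))
  expect_equal(unname(eff1$efficiency), c(1, 1))
  # empty channel flagged
  eff0 <- probe_efficiency(t1, spot_table(), run_config())
  expect_true(length(eff0$flag) > 0)
  expect_true(is.na(eff0$efficiency[["channel2"]]))
})
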