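# Shared fixtures and independent oracles, built in code at test time.

# small packed-cell embryo used across tests
small_embryo <- function(shape = c(24, 72, 72), n_cells = 8L, seed = 3L,
                         voxel = c(0.4, 0.13, 0.13), ...) {
  generate_embryo(embryo_geometry(volume_shape = shape, voxel_size_um = voxel,
                                  n_cells = n_cells, seed = seed), ...)
}

# detection configuration matched to the synthetic intensity law
scene_config <- function(...) {
  base <- list(detect_threshold = 30, detect_split_h = 30)
  over <- list(...)
  base[names(over)] <- over
  do.call(run_config, base)
}

# wrap generator ground truth as a spot_table (for matching against truth)
truth_to_spot_table <- function(truth, channel = "truth") {
  spot_table(data.frame(
    id = truth$id, channel = channel,
    z_um = truth$z_um, y_um = truth$y_um, x_um = truth$x_um,
    peak_intensity = 1, integrated_intensity = 1,
    category = "unassigned", membrane_distance_um = NA_real_,
    stringsAsFactors = FALSE
  ))
}

# brute-force distance to the nearest boundary voxel centre (O(N * B)),
# independent of the package's distance transform
brute_force_distance <- function(feature, spacing) {
  d <- dim(feature)
  stopifnot(any(feature))
  co_all <- arrayInd(seq_len(prod(d)), d)
  pos_all <- sweep(co_all - 1, 2, spacing, `*`)
  bidx <- which(feature)
  bpos <- sweep(arrayInd(bidx, d) - 1, 2, spacing, `*`)
  best <- rep(Inf, nrow(pos_all))
  for (b in seq_len(nrow(bpos))) {
    dd <- (pos_all[, 1] - bpos[b, 1])^2 + (pos_all[, 2] - bpos[b, 2])^2 +
      (pos_all[, 3] - bpos[b, 3])^2
    best <- pmin(best, dd)
  }
  array(sqrt(best), d)
}

# greedy maximal-overlap label agreement (relabelling-invariant)
label_agreement <- function(a, b) {
  sel <- a > 0 | b > 0
  ta <- table(a[sel], b[sel])
  tot <- sum(ta)
  s <- 0
  repeat {
    m <- which(ta == max(ta), arr.ind = TRUE)[1, , drop = FALSE]
    if (ta[m] == 0) break
    s <- s + ta[m]
    ta[m[1], ] <- 0
    ta[, m[2]] <- 0
    if (all(ta == 0)) break
  }
  s / tot
}

# maximum-cardinality bipartite matching within a radius (augmenting paths);
# independent oracle for the pair count of match_spots
max_matching_count <- function(pa, pb, radius) {
  n_a <- nrow(pa)
  n_b <- nrow(pb)
  adj <- vector("list", n_a)
  for (i in seq_len(n_a)) {
    dd <- sqrt(colSums((t(pb) - pa[i, ])^2))
    adj[[i]] <- which(dd <= radius)
  }
  match_b <- rep(0L, n_b)
  n <- 0L
  for (i0 in seq_len(n_a)) {
    seen <- rep(FALSE, n_b)
    aug <- function(i) {
      for (j in adj[[i]]) {
        if (!seen[j]) {
          seen[j] <<- TRUE
          if (match_b[j] == 0L || aug(match_b[j])) {
            match_b[j] <<- i
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(i0)) n <- n + 1L
  }
  n
}
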