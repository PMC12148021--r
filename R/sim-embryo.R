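#' Geometry of a synthetic embryo scene
#'
#' Describes the voxel grid and the embryo ellipsoid used by
#' [generate_embryo()]. Defaults emulate a packed 30-60 cell stage embryo
#' imaged with 0.4 um z-steps and ~0.13 um pixels, scaled down to a desk-size
#' volume.
#'
#' @param volume_shape voxels (z,y,x).
#' @param voxel_size_um physical voxel size (z,y,x) in um; anisotropy allowed.
#' @param semi_axes_um embryo ellipsoid semi-axes (z,y,x) in um; default 85%
#'   of the half-extent of the volume.
#' @param center_um ellipsoid centre in um; default the volume centre.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; the whole scene is deterministic given it.
#' @return an `embryo_geometry` list.
#' @export
embryo_geometry <- function(volume_shape = c(40L, 120L, 120L),
                            voxel_size_um = c(0.4, 0.13, 0.13),
                            semi_axes_um = NULL,
                            center_um = NULL,
                            n_cells = 16L,
                            seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 3L))
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be 3 positive values (z,y,x)")
  }
  extent <- (volume_shape - 1L) * voxel_size_um
  if (is.null(center_um)) center_um <- extent / 2
  if (is.null(semi_axes_um)) semi_axes_um <- 0.85 * extent / 2
  if (any(semi_axes_um <= 0)) stop("semi axes must be positive")
  if (n_cells < 1L) stop("n_cells must be >= 1")
  structure(list(volume_shape = volume_shape, voxel_size_um = voxel_size_um,
                 center_um = center_um, semi_axes_um = semi_axes_um,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "embryo_geometry")
}

# physical coordinates (um) of all voxel centres, as a 3-column matrix chunk-free
voxel_coords_um <- function(shape, vs) {
  z <- index_to_um(seq_len(shape[1]), vs[1])
  y <- index_to_um(seq_len(shape[2]), vs[2])
  x <- index_to_um(seq_len(shape[3]), vs[3])
  list(z = z, y = y, x = x)
}

ellipsoid_mask <- function(geom) {
  co <- voxel_coords_um(geom$volume_shape, geom$voxel_size_um)
  dz2 <- ((co$z - geom$center_um[1]) / geom$semi_axes_um[1])^2
  dy2 <- ((co$y - geom$center_um[2]) / geom$semi_axes_um[2])^2
  dx2 <- ((co$x - geom$center_um[3]) / geom$semi_axes_um[3])^2
  q <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  q <= 1
}

#' Generate a synthetic embryo: membrane channel, cell labels and mask
#'
#' Cells are a seeded tessellation of the embryo ellipsoid: `n_cells` seed
#' points are drawn uniformly inside the ellipsoid and every interior voxel
#' is assigned to its nearest seed in physical (um) distance. The membrane
#' channel is bright exactly on the inter-cell / surface boundary voxels,
#' blurred by an anisotropic Gaussian PSF stand-in, offset by a background
#' level, and optionally corrupted by Poisson-Gaussian camera noise (off by
#' default so tests can be exact).
#'
#' @param geometry an [embryo_geometry()].
#' @param membrane_peak boundary intensity before blurring (ADU).
#' @param background_level constant offset (ADU).
#' @param psf_sigma_um PSF sigma (z,y,x) in um.
#' @param noise `NULL` (off) or `list(gain =, read_sd =)` for Poisson-Gaussian
#'   noise: `gain * Poisson(x / gain) + Normal(0, read_sd)`.
#' @return list with `membrane` ([image_stack()]), `labels`
#'   ([label_volume()]), `mask` (logical array) and `geometry`.
#' @export
generate_embryo <- function(geometry,
                            membrane_peak = 1000,
                            background_level = 50,
                            psf_sigma_um = c(0.35, 0.15, 0.15),
                            noise = NULL) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  mask <- ellipsoid_mask(geometry)
  n_in <- sum(mask)
  if (n_in < geometry$n_cells * 27L) {
    stop("volume too small: ", n_in, " interior voxels cannot hold ",
         geometry$n_cells, " cells")
  }
  vs <- geometry$voxel_size_um
  labels <- withr::with_seed(geometry$seed, {
    seeds <- sample_in_ellipsoid(geometry, geometry$n_cells)
    assign_nearest_seed(mask, vs, seeds)
  })
  lv <- label_volume(labels, vs)
  memb <- array(0, dim(mask))
  memb[boundary_mask(lv)] <- membrane_peak
  memb <- gaussian_smooth(memb, vs, psf_sigma_um) + background_level
  if (!is.null(noise)) {
    memb <- withr::with_seed(geometry$seed + 1L,
                             apply_camera_noise(memb, noise))
  }
  list(membrane = image_stack(memb, vs), labels = lv, mask = mask,
       geometry = geometry)
}

sample_in_ellipsoid <- function(geom, n) {
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    cand <- cbind(runif(4 * n, -1, 1), runif(4 * n, -1, 1), runif(4 * n, -1, 1))
    keep <- rowSums(cand^2) <= 1
    pts <- sweep(cand[keep, , drop = FALSE], 2, geom$semi_axes_um, `*`)
    pts <- sweep(pts, 2, geom$center_um, `+`)
    out <- rbind(out, pts)
  }
  out[seq_len(n), , drop = FALSE]
}

assign_nearest_seed <- function(mask, vs, seeds) {
  d <- dim(mask)
  idx <- which(mask)
  co <- arrayInd(idx, d)
  pz <- index_to_um(co[, 1], vs[1])
  py <- index_to_um(co[, 2], vs[2])
  px <- index_to_um(co[, 3], vs[3])
  best <- rep(Inf, length(idx))
  lab <- integer(length(idx))
  for (s in seq_len(nrow(seeds))) {
    dd <- (pz - seeds[s, 1])^2 + (py - seeds[s, 2])^2 + (px - seeds[s, 3])^2
    upd <- dd < best
    best[upd] <- dd[upd]
    lab[upd] <- s
  }
  out <- array(0L, d)
  out[idx] <- lab
  out
}

apply_camera_noise <- function(x, noise) {
  gain <- noise$gain %||% 1
  read_sd <- noise$read_sd %||% 0
  y <- gain * rpois(length(x), pmax(x, 0) / gain)
  y <- y + rnorm(length(x), 0, read_sd)
  array(y, dim(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spot placement and rendering parameters
#'
#' @param n_spots number of bright (translation-class) spots.
#' @param p_membrane probability that a spot is drawn from the
#'   membrane-proximal band (distance within `band_width_um` of the
#'   membrane); the remainder are drawn from the interior beyond the band.
#'   `NULL` places all spots uniformly over the cell volume with no band
#'   conditioning (the spatially random null scenario).
#' @param band_width_um proximity band width, default 0.35 um.
#' @param intensity_law lognormal peak-amplitude law for translation spots:
#'   `list(median =, sdlog =)` (ADU).
#' @param n_mature number of additional dim mature-protein spots, placed
#'   uniformly inside cells.
#' @param mature_intensity_law lognormal law for the dim class.
#' @param psf_sigma_um rendering sigma (z,y,x) um.
#' @param background_level constant offset (ADU).
#' @param noise `NULL` or `list(gain =, read_sd =)` as in [generate_embryo()].
#' @param min_separation_um minimum 3D centre-to-centre distance between
#'   spots (0 = unconstrained, the default; used to build well-separated
#'   scenes for detection operating-point tests).
#' @param seed integer seed.
#' @return a `spot_params` list.
#' @export
spot_params <- function(n_spots = 200L,
                        p_membrane = 0.5,
                        band_width_um = 0.35,
                        intensity_law = list(median = 800, sdlog = 0.3),
                        n_mature = 0L,
                        mature_intensity_law = list(median = 60, sdlog = 0.3),
                        psf_sigma_um = c(0.35, 0.15, 0.15),
                        background_level = 20,
                        noise = NULL,
                        min_separation_um = 0,
                        seed = 1L) {
  if (!is.null(p_membrane) && (p_membrane < 0 || p_membrane > 1)) {
    stop("p_membrane must be in [0,1] (or NULL for unconditioned placement)")
  }
  if (band_width_um <= 0) stop("band_width_um must be positive")
  if (any(psf_sigma_um <= 0)) stop("psf_sigma_um must be positive per axis")
  if (min_separation_um < 0) stop("min_separation_um must be nonnegative")
  structure(list(n_spots = as.integer(n_spots), p_membrane = p_membrane,
                 band_width_um = band_width_um, intensity_law = intensity_law,
                 n_mature = as.integer(n_mature),
                 mature_intensity_law = mature_intensity_law,
                 psf_sigma_um = psf_sigma_um,
                 background_level = background_level, noise = noise,
                 min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "spot_params")
}

#' Place and render spots inside a segmented synthetic embryo
#'
#' Membrane-proximal spots are sampled uniformly from the band
#' `{0 <= d <= band_width}` of the distance-to-membrane map, the rest
#' uniformly from the interior beyond the band; each spot is rendered as an
#' anisotropic Gaussian at a continuous (sub-voxel) centre. Ground-truth
#' membrane distances are the trilinearly interpolated distance-map values
#' at the exact centres -- i.e. the same quantity the analysis pipeline
#' estimates, so parameter-recovery tests isolate detection error.
#'
#' @param labels a [label_volume()] (typically from [generate_embryo()]).
#' @param params a [spot_params()].
#' @return list with `spots` ([image_stack()]), `truth` (data frame: id,
#'   class, z/y/x_um, membrane_distance_um, amplitude) and `dmap` (the
#'   [distance_map()] used for placement).
#' @export
place_and_render_spots <- function(labels, params) {
  stopifnot(inherits(labels, "label_volume"), inherits(params, "spot_params"))
  vs <- labels$voxel_size
  dmap <- distance_to_membrane(labels)
  inside <- labels$labels > 0L
  band <- inside & dmap$dist <= params$band_width_um
  interior <- inside & dmap$dist > params$band_width_um
  if (!is.null(params$p_membrane)) {
    if (params$p_membrane > 0 && !any(band)) {
      stop("no voxels within ", params$band_width_um, " um of the membrane")
    }
    if (params$p_membrane < 1 && !any(interior)) {
      stop("no interior voxels beyond the proximity band")
    }
  }

  res <- withr::with_seed(params$seed, {
    msep <- params$min_separation_um
    n_tr <- params$n_spots
    if (is.null(params$p_membrane)) {
      centers <- sample_region(n_tr, inside, dmap, vs, function(d) TRUE,
                               labels, min_sep = msep)
    } else {
      is_mem <- runif(n_tr) < params$p_membrane
      centers_mem <- sample_region(sum(is_mem), band, dmap, vs,
                                   function(d) d <= params$band_width_um,
                                   labels, min_sep = msep)
      centers_int <- sample_region(sum(!is_mem), interior, dmap, vs,
                                   function(d) d > params$band_width_um,
                                   labels, min_sep = msep,
                                   existing = centers_mem)
      centers <- matrix(0, n_tr, 3)
      centers[is_mem, ] <- centers_mem
      centers[!is_mem, ] <- centers_int
    }
    amps <- rlnorm(n_tr, log(params$intensity_law$median),
                   params$intensity_law$sdlog)
    cls <- rep("translation", n_tr)
    if (params$n_mature > 0L) {
      cm <- sample_region(params$n_mature, inside, dmap, vs,
                          function(d) TRUE, labels, min_sep = msep,
                          existing = centers)
      centers <- rbind(centers, cm)
      amps <- c(amps, rlnorm(params$n_mature,
                             log(params$mature_intensity_law$median),
                             params$mature_intensity_law$sdlog))
      cls <- c(cls, rep("mature", params$n_mature))
    }
    list(centers = centers, amps = amps, cls = cls)
  })

  img <- render_gaussian_spots(dim(labels$labels), vs, res$centers, res$amps,
                               params$psf_sigma_um) + params$background_level
  if (!is.null(params$noise)) {
    img <- withr::with_seed(params$seed + 1L,
                            apply_camera_noise(img, params$noise))
  }
  truth <- data.frame(
    id = seq_along(res$amps),
    class = res$cls,
    z_um = res$centers[, 1], y_um = res$centers[, 2], x_um = res$centers[, 3],
    membrane_distance_um = interp_map(dmap, res$centers),
    amplitude = res$amps,
    stringsAsFactors = FALSE
  )
  list(spots = image_stack(img, vs), truth = truth, dmap = dmap)
}

# rejection-sample continuous centres whose interpolated distance satisfies
# `accept` and whose containing voxel is inside a cell; candidate voxels are
# drawn uniformly from `region`, then jittered within the voxel. With
# min_sep > 0, candidates closer than min_sep to any accepted or `existing`
# centre are rejected (greedy, order-dependent but seed-deterministic).
sample_region <- function(n, region, dmap, vs, accept, labels,
                          min_sep = 0, existing = matrix(0, 0, 3)) {
  out <- matrix(0, 0, 3)
  if (n == 0L) return(matrix(0, 0, 3))
  vox <- which(region)
  if (!length(vox)) stop("empty placement region")
  d <- dim(region)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 200L) stop("placement rejection sampling failed to converge")
    m <- 2L * (n - nrow(out)) + 8L
    pick <- vox[sample.int(length(vox), m, replace = TRUE)]
    co <- arrayInd(pick, d)
    jit <- matrix(runif(3 * m, -0.5, 0.5), m, 3)
    idx_cont <- co + jit
    # clamp to valid interpolation range
    idx_cont <- pmin(pmax(idx_cont, 1), matrix(rep(d, each = m), m, 3))
    pos <- sweep(idx_cont - 1, 2, vs, `*`)
    dist <- interp_map(dmap, pos)
    lab_ok <- labels$labels[cbind(round(idx_cont[, 1]), round(idx_cont[, 2]),
                                  round(idx_cont[, 3]))] > 0L
    ok <- accept(dist) & lab_ok
    cand <- pos[ok, , drop = FALSE]
    if (min_sep > 0) {
      for (j in seq_len(nrow(cand))) {
        taken <- rbind(existing, out)
        if (nrow(taken)) {
          d2 <- (taken[, 1] - cand[j, 1])^2 + (taken[, 2] - cand[j, 2])^2 +
            (taken[, 3] - cand[j, 3])^2
          if (min(d2) < min_sep^2) next
        }
        out <- rbind(out, cand[j, , drop = FALSE])
        if (nrow(out) == n) break
      }
    } else {
      out <- rbind(out, cand)
    }
  }
  out[seq_len(n), , drop = FALSE]
}

# trilinear interpolation of a distance map (or any array sharing its grid)
# at physical positions (um); positions are clamped to the grid
interp_map <- function(dmap, pos_um) {
  arr <- if (inherits(dmap, "distance_map")) dmap$dist else dmap
  vs <- voxel_size(dmap)
  d <- dim(arr)
  if (is.null(dim(pos_um))) pos_um <- matrix(pos_um, ncol = length(d))
  idx <- sweep(pos_um, 2, vs, `/`) + 1
  idx <- pmin(pmax(idx, 1), matrix(rep(d, each = nrow(idx)), nrow(idx)))
  i0 <- pmin(floor(idx), matrix(rep(d - 1L, each = nrow(idx)), nrow(idx)))
  i0 <- pmax(i0, 1)
  fr <- idx - i0
  out <- numeric(nrow(idx))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dx) fr[, 3] else 1 - fr[, 3])
    out <- out + w * arr[cbind(i0[, 1] + dz, i0[, 2] + dy, i0[, 3] + dx)]
  }
  out
}

# additive rendering of anisotropic Gaussian point sources (separable patches)
render_gaussian_spots <- function(shape, vs, centers_um, amplitudes,
                                  psf_sigma_um) {
  img <- array(0, shape)
  if (!nrow(centers_um)) return(img)
  sig_vox <- psf_sigma_um / vs
  r <- ceiling(4 * sig_vox)
  for (i in seq_len(nrow(centers_um))) {
    cidx <- um_to_index(centers_um[i, ], vs)
    lo <- pmax(1L, floor(cidx - r))
    hi <- pmin(shape, ceiling(cidx + r))
    if (any(hi < lo)) next
    gz <- exp(-((lo[1]:hi[1]) - cidx[1])^2 / (2 * sig_vox[1]^2))
    gy <- exp(-((lo[2]:hi[2]) - cidx[2])^2 / (2 * sig_vox[2]^2))
    gx <- exp(-((lo[3]:hi[3]) - cidx[3])^2 / (2 * sig_vox[3]^2))
    patch <- amplitudes[i] * outer(outer(gz, gy), gx)
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + patch
  }
  img
}

#' Synthetic nuclei for re-localization scenes
#'
#' Places one spherical nucleus per cell at the cell's centroid (radius
#' clipped so the sphere stays inside the volume). The nuclear surface is
#' the boundary voxel set of the resulting mask.
#'
#' @param labels a [label_volume()].
#' @param radius_um nuclear radius in um.
#' @return list with `mask` (logical array), `dmap` (distance to the nuclear
#'   surface, a [distance_map()]) and `centers_um`.
#' @export
generate_nuclei <- function(labels, radius_um = 1.2) {
  stopifnot(inherits(labels, "label_volume"))
  vs <- labels$voxel_size
  d <- dim(labels$labels)
  co <- voxel_coords_um(d, vs)
  mask <- array(FALSE, d)
  ids <- sort(unique(as.vector(labels$labels)))
  ids <- ids[ids != 0L]
  centers <- matrix(0, length(ids), 3)
  for (k in seq_along(ids)) {
    idx <- which(labels$labels == ids[k])
    ci <- arrayInd(idx, d)
    cen <- c(mean(index_to_um(ci[, 1], vs[1])),
             mean(index_to_um(ci[, 2], vs[2])),
             mean(index_to_um(ci[, 3], vs[3])))
    centers[k, ] <- cen
    q <- outer(outer(((co$z - cen[1]) / radius_um)^2,
                     ((co$y - cen[2]) / radius_um)^2, `+`),
               ((co$x - cen[3]) / radius_um)^2, `+`)
    mask <- mask | (q <= 1)
  }
  nl <- label_volume(array(as.integer(mask), d), vs)
  list(mask = mask, dmap = distance_to_membrane(nl), centers_um = centers)
}

#' Place spots with known nuclear-pore / membrane / cytosol classes
#'
#' Ground-truth scene for the re-localization categorization: each spot's
#' class is drawn from `class_probs` and its position sampled so that the
#' distance-rule categorization recovers the class exactly in the noiseless
#' limit (nuclear-pore spots within the cutoff of the nuclear surface;
#' membrane spots within the cutoff of the membrane but beyond it from
#' nuclei; cytosol spots beyond the cutoff from both).
#'
#' @param labels a [label_volume()].
#' @param nuclei output of [generate_nuclei()].
#' @param class_probs probabilities for (nuclear_pore, membrane, cytosol);
#'   must sum to 1.
#' @param n_spots number of spots.
#' @param cutoff_um categorization cutoff in um.
#' @param seed integer seed.
#' @return data frame: id, class, z/y/x_um.
#' @export
place_categorized_spots <- function(labels, nuclei,
                                    class_probs = c(0.8, 0.1, 0.1),
                                    n_spots = 500L, cutoff_um = 0.35,
                                    seed = 1L) {
  stopifnot(inherits(labels, "label_volume"))
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  mem <- distance_to_membrane(labels)
  nuc <- nuclei$dmap
  inside <- labels$labels > 0L & !nuclei$mask
  reg <- list(
    nuclear_pore = inside & nuc$dist <= cutoff_um,
    membrane = inside & mem$dist <= cutoff_um & nuc$dist > cutoff_um,
    cytosol = inside & mem$dist > cutoff_um & nuc$dist > cutoff_um
  )
  for (nm in names(reg)) {
    if (class_probs[match(nm, names(reg))] > 0 && !any(reg[[nm]])) {
      stop("no voxels available for class ", nm)
    }
  }
  withr::with_seed(seed, {
    cls <- sample(names(reg), n_spots, replace = TRUE, prob = class_probs)
    pos <- matrix(0, n_spots, 3)
    rule <- list(
      nuclear_pore = function(p) interp_map(nuc, p) <= cutoff_um,
      membrane = function(p) interp_map(mem, p) <= cutoff_um &
        interp_map(nuc, p) > cutoff_um,
      cytosol = function(p) interp_map(mem, p) > cutoff_um &
        interp_map(nuc, p) > cutoff_um
    )
    for (nm in names(reg)) {
      k <- cls == nm
      if (!any(k)) next
      pos[k, ] <- sample_region_by_rule(sum(k), reg[[nm]], rule[[nm]],
                                        labels, nuclei)
    }
    data.frame(id = seq_len(n_spots), class = cls,
               z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
               stringsAsFactors = FALSE)
  })
}

sample_region_by_rule <- function(n, region, rule, labels, nuclei) {
  vs <- labels$voxel_size
  d <- dim(region)
  vox <- which(region)
  out <- matrix(0, 0, 3)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 500L) stop("categorized placement failed to converge")
    m <- 2L * (n - nrow(out)) + 8L
    pick <- vox[sample.int(length(vox), m, replace = TRUE)]
    co <- arrayInd(pick, d) + matrix(runif(3 * m, -0.5, 0.5), m, 3)
    co <- pmin(pmax(co, 1), matrix(rep(d, each = m), m, 3))
    pos <- sweep(co - 1, 2, vs, `*`)
    ri <- cbind(round(co[, 1]), round(co[, 2]), round(co[, 3]))
    ok <- rule(pos) & labels$labels[ri] > 0L & !nuclei$mask[ri]
    out <- rbind(out, pos[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
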