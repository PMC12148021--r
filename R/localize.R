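#' Fill per-spot membrane distances from a distance map
#'
#' Samples the distance-to-membrane map at each spot's sub-voxel centre by
#' trilinear (or bilinear) interpolation and fills the
#' `membrane_distance_um` column. Spots outside the map are an error.
#'
#' @param spots a [spot_table()] with 3D (or 2D) centres in um.
#' @param dmap a [distance_map()] sharing the coordinate frame.
#' @return the annotated [spot_table()].
#' @export
spot_membrane_distances <- function(spots, dmap) {
  spots <- spot_table(spots)
  stopifnot(inherits(dmap, "distance_map"))
  if (nrow(spots) == 0L) return(spots)
  d <- dim(dmap$dist)
  vs <- dmap$voxel_size
  nd <- length(d)
  pos <- if (nd == 3L) cbind(spots$z_um, spots$y_um, spots$x_um) else
    cbind(spots$y_um, spots$x_um)
  extent <- (d - 1) * vs
  tol <- 1e-9
  inb <- rep(TRUE, nrow(pos))
  for (a in seq_len(nd)) {
    inb <- inb & pos[, a] >= -tol & pos[, a] <= extent[a] + tol
  }
  if (!all(inb)) {
    stop(sum(!inb), " spot(s) fall outside the distance map")
  }
  spots$membrane_distance_um <- interp_map_nd(dmap, pos)
  spots
}

# trilinear/bilinear interpolation for 2D or 3D maps
interp_map_nd <- function(dmap, pos_um) {
  arr <- dmap$dist
  nd <- length(dim(arr))
  if (nd == 3L) return(interp_map(dmap, pos_um))
  vs <- dmap$voxel_size
  d <- dim(arr)
  idx <- sweep(pos_um, 2, vs, `/`) + 1
  idx <- pmin(pmax(idx, 1), matrix(rep(d, each = nrow(idx)), nrow(idx)))
  i0 <- pmax(pmin(floor(idx), matrix(rep(d - 1L, each = nrow(idx)), nrow(idx))), 1)
  fr <- idx - i0
  out <- numeric(nrow(idx))
  for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dy) fr[, 1] else 1 - fr[, 1]) * (if (dx) fr[, 2] else 1 - fr[, 2])
    out <- out + w * arr[cbind(i0[, 1] + dy, i0[, 2] + dx)]
  }
  out
}

#' Membrane-proximity fraction of translation spots
#'
#' The proportion of spots whose distance to the nearest membrane is within
#' the 0-0.35 um band (the cutoff is inclusive: the printed range is
#' closed). Zero spots are an error; embryo inclusion (at least 25 spots)
#' is the caller's decision via [embryo_inclusion()].
#'
#' @param spots a [spot_table()] with `membrane_distance_um` filled.
#' @param cutoff_um proximity band, default 0.35 um.
#' @param condition label recorded in the result (e.g. `"observed"`,
#'   `"zflip_null"`).
#' @return a one-row data frame: n_spots, n_within, fraction_within,
#'   cutoff_um, condition.
#' @export
proximity_fraction <- function(spots, cutoff_um = 0.35,
                               condition = "observed") {
  spots <- spot_table(spots)
  if (nrow(spots) == 0L) stop("no spots: proximity fraction undefined")
  if (anyNA(spots$membrane_distance_um)) {
    stop("membrane distances missing; run spot_membrane_distances() first")
  }
  n_within <- sum(spots$membrane_distance_um <= cutoff_um)
  data.frame(n_spots = nrow(spots), n_within = n_within,
             fraction_within = n_within / nrow(spots),
             cutoff_um = cutoff_um, condition = condition,
             stringsAsFactors = FALSE)
}

#' z-flip randomized null control
#'
#' Reverses the plane order of the spot channel along the optical (z) axis
#' while the membrane channel and its segmentation stay fixed, destroying
#' the spot-membrane registration but keeping the spots' axial envelope
#' inside the embryo. The full detection + distance pipeline is then re-run
#' on the flipped stack exactly as on the original, so any computational
#' bias applies to both.
#'
#' @param stack 3D single-channel [image_stack()].
#' @return the flipped [image_stack()].
#' @export
zflip_null <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (length(d) != 3L) stop("zflip_null needs a 3D stack")
  image_stack(stack$data[d[1]:1, , , drop = FALSE], stack$voxel_size,
              frame_interval = stack$frame_interval)
}

#' Run the membrane-proximity analysis on one embryo
#'
#' Convenience wrapper chaining the pipeline the way the per-embryo analysis
#' runs it: denoise, detect in 3D, optionally gate, drop excluded regions,
#' measure distances against the segmentation's distance map, and compute
#' the proximity fraction. Used identically for the observed stack and its
#' z-flipped null.
#'
#' @param spot_channel 3D [image_stack()].
#' @param dmap [distance_map()] from the (unflipped) segmentation.
#' @param config a [run_config()].
#' @param denoise_sigma_um smoothing before detection (0 = none).
#' @param gate integrated-intensity gate in ADU (`NULL` = no gate).
#' @param exclude optional exclusion mask.
#' @param condition condition label for the result row.
#' @return list with `spots` (annotated [spot_table()]) and `result`
#'   (the [proximity_fraction()] row).
#' @export
proximity_pipeline <- function(spot_channel, dmap, config = run_config(),
                               denoise_sigma_um = 0, gate = NULL,
                               exclude = NULL, condition = "observed") {
  st <- if (any(denoise_sigma_um > 0)) {
    denoise_spot_channel(spot_channel, denoise_sigma_um)
  } else spot_channel
  spots <- detect_spots(st, config, exclude = exclude)
  if (!is.null(gate)) spots <- gate_by_intensity(spots, gate)
  spots <- spot_membrane_distances(spots, dmap)
  list(spots = spots,
       result = proximity_fraction(spots, config$proximity_cutoff_um,
                                   condition))
}

#' Categorize spots as nuclear pore / membrane / cytosol
#'
#' Distance-rule replacement for visual categorization: a spot is
#' `nuclear_pore` if its distance to the nuclear surface is within the
#' cutoff, else `membrane` if its membrane distance is within the cutoff,
#' else `cytosol`. Without a nuclear map (no nuclear marker), spots are
#' categorized over membrane/cytosol only. Spots inside excluded (mitotic)
#' regions should be removed upstream via [detect_spots()]'s `exclude`.
#'
#' @param spots a [spot_table()].
#' @param dmap_membrane membrane [distance_map()].
#' @param dmap_nuclear nuclear-surface [distance_map()] or `NULL`.
#' @param cutoff_um categorization cutoff, default the proximity cutoff.
#' @return list with `spots` (category column filled) and `counts`/
#'   `fractions` over the categories (fractions sum to 1).
#' @export
categorize_spots <- function(spots, dmap_membrane, dmap_nuclear = NULL,
                             cutoff_um = 0.35) {
  spots <- spot_membrane_distances(spots, dmap_membrane)
  n <- nrow(spots)
  if (n == 0L) stop("no spots to categorize")
  nuc_d <- if (!is.null(dmap_nuclear)) {
    pos <- cbind(spots$z_um, spots$y_um, spots$x_um)
    interp_map_nd(dmap_nuclear, pos)
  } else rep(Inf, n)
  cat <- ifelse(nuc_d <= cutoff_um, "nuclear_pore",
                ifelse(spots$membrane_distance_um <= cutoff_um,
                       "membrane", "cytosol"))
  spots$category <- cat
  counts <- c(nuclear_pore = sum(cat == "nuclear_pore"),
              membrane = sum(cat == "membrane"),
              cytosol = sum(cat == "cytosol"))
  list(spots = spots, counts = counts, fractions = counts / n)
}

#' Re-localization efficiency summary across embryos
#'
#' Per-embryo category percentages (each category's spot count divided by
#' the embryo's total) plus the per-condition mean and standard deviation.
#' Embryos failing the inclusion rule (more than `min_spots` translation
#' spots, strict) are excluded from the summary and listed.
#'
#' @param category_results list of [categorize_spots()] results (one per
#'   embryo), or list of named count vectors.
#' @param min_spots strict inclusion threshold, default 7.
#' @return list with `per_embryo` (data frame of percentages), `summary`
#'   (mean and sd per category over included embryos) and `excluded`
#'   (integer indices of excluded embryos).
#' @export
relocalization_report <- function(category_results, min_spots = 7L) {
  counts <- lapply(category_results, function(r) {
    if (is.list(r) && !is.null(r$counts)) r$counts else r
  })
  cats <- c("nuclear_pore", "membrane", "cytosol")
  per <- do.call(rbind, lapply(seq_along(counts), function(i) {
    ct <- counts[[i]][cats]
    ct[is.na(ct)] <- 0
    total <- sum(ct)
    data.frame(embryo = i, n_spots = total,
               nuclear_pore = 100 * ct[["nuclear_pore"]] / total,
               membrane = 100 * ct[["membrane"]] / total,
               cytosol = 100 * ct[["cytosol"]] / total,
               included = embryo_inclusion(total, min_spots, strict = TRUE)[1],
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  inc <- per[per$included, , drop = FALSE]
  summ <- data.frame(
    category = cats,
    mean_pct = vapply(cats, function(cc) mean(inc[[cc]]), numeric(1)),
    sd_pct = vapply(cats, function(cc) sd(inc[[cc]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_embryo = per, summary = summ,
       excluded = per$embryo[!per$included])
}
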