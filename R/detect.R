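#' Maximum-intensity projection over a contiguous z-slab
#'
#' Voxel-wise maximum over `n_slices` consecutive z-planes starting at
#' `anchor`. The overlap assay uses 6-slice projections and the counting
#' assay 5-slice projections (see [run_config()]).
#'
#' @param stack 3D [image_stack()].
#' @param n_slices number of planes in the slab (1 <= n <= depth).
#' @param anchor first plane of the slab (1-based).
#' @return a 2D [image_stack()] carrying the in-plane calibration.
#' @export
max_project <- function(stack, n_slices, anchor = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (length(d) != 3L) stop("max_project needs a 3D stack")
  n_slices <- as.integer(n_slices)
  anchor <- as.integer(anchor)
  if (n_slices < 1L || anchor < 1L || anchor + n_slices - 1L > d[1]) {
    stop("projection slab [", anchor, ", ", anchor + n_slices - 1L,
         "] outside the stack depth ", d[1])
  }
  slab <- stack$data[anchor:(anchor + n_slices - 1L), , , drop = FALSE]
  proj <- apply(slab, c(2, 3), max)
  image_stack(proj, stack$voxel_size[c("y", "x")],
              frame_interval = stack$frame_interval)
}

#' Detect diffraction-limited spots (2D or 3D)
#'
#' Band-pass blob detection: a difference-of-Gaussians response at the
#' configured physical scale (`detect_scale_um`), thresholded at
#' `detect_threshold` (the analogue of a blob finder's probability
#' threshold), with merged maxima split by a tolerance watershed whose
#' depth is `detect_split_h` (the split sensitivity: maxima whose prominence
#' above their common saddle is below it collapse into one spot). Sub-voxel
#' centres are response-weighted centroids; `integrated_intensity` is the
#' background-corrected raw sum over an ellipsoidal neighbourhood of radius
#' 3 scale, with the local background taken as the median of a surrounding
#' shell (3-5 scale).
#'
#' @param image an [image_stack()] (2D or 3D), typically after
#'   [denoise_spot_channel()].
#' @param config a [run_config()]; uses `detect_scale_um`,
#'   `detect_threshold`, `detect_split_h`.
#' @param channel channel name recorded in the output table.
#' @param exclude optional logical array (e.g. from [exclusion_mask()]);
#'   detections whose centre falls in it are dropped.
#' @return a [spot_table()].
#' @export
detect_spots <- function(image, config = run_config(), channel = "spots",
                         exclude = NULL) {
  stopifnot(inherits(image, "image_stack"))
  d <- dim(image$data)
  nd <- length(d)
  vs <- image$voxel_size
  scale_um <- rep_len(config$detect_scale_um, nd)
  if (nd == 2L && length(config$detect_scale_um) == 3L) {
    scale_um <- config$detect_scale_um[2:3] # drop the z scale on projections
  }
  if (any(scale_um < vs)) {
    warning("detection scale below one voxel on some axis; clamping")
    scale_um <- pmax(scale_um, vs)
  }

  g1 <- gaussian_smooth(image$data, vs, scale_um)
  g2 <- gaussian_smooth(image$data, vs, 1.6 * scale_um)
  resp <- g1 - g2

  mask <- resp > config$detect_threshold
  if (!any(mask)) return(spot_table())
  labels <- cpp_tolerance_watershed(as.numeric(resp), d,
                                    config$detect_split_h, as.logical(mask))
  labels <- array(labels, d)
  n_lab <- max(labels)
  if (n_lab == 0L) return(spot_table())

  vox <- which(labels > 0L)
  lab_f <- factor(labels[vox], levels = seq_len(n_lab))
  resp_v <- resp[vox]
  co <- arrayInd(vox, d)
  # response-above-threshold weighted centroid per label (sub-voxel)
  w <- resp_v - config$detect_threshold
  wsum <- tapply(w, lab_f, sum)
  centers_idx <- matrix(0, n_lab, nd)
  for (a in seq_len(nd)) {
    centers_idx[, a] <- tapply(w * co[, a], lab_f, sum) / wsum
  }
  peak_resp <- tapply(resp_v, lab_f, max)

  meas <- measure_spots(image$data, vs, centers_idx, scale_um)
  centers_um <- sweep(centers_idx - 1, 2, vs, `*`)

  keep <- rep(TRUE, n_lab)
  if (!is.null(exclude)) {
    ridx <- round(centers_idx)
    ridx <- pmin(pmax(ridx, 1), matrix(rep(d, each = n_lab), n_lab))
    keep <- !exclude[ridx]
  }

  n_keep <- sum(keep)
  if (n_keep == 0L) return(spot_table())
  df <- data.frame(
    id = seq_len(n_keep), channel = rep(channel, n_keep),
    z_um = if (nd == 3L) centers_um[keep, 1] else rep(NA_real_, n_keep),
    y_um = centers_um[keep, nd - 1], x_um = centers_um[keep, nd],
    peak_intensity = meas$peak[keep],
    integrated_intensity = pmax(meas$integrated[keep], 0),
    category = rep("unassigned", n_keep),
    membrane_distance_um = rep(NA_real_, n_keep),
    stringsAsFactors = FALSE
  )
  out <- spot_table(df)
  attr(out, "response_peak") <- as.numeric(peak_resp[keep])
  out
}

# ellipsoidal-neighbourhood photometry around rounded centres:
# integrated = sum(raw within 3*scale) - n * median(shell 3-5 scale)
measure_spots <- function(data, vs, centers_idx, scale_um) {
  d <- dim(data)
  nd <- length(d)
  r_in_vox <- 3 * scale_um / vs
  r_out_vox <- 5 * scale_um / vs
  ranges <- lapply(seq_len(nd), function(a) -ceiling(r_out_vox[a]):ceiling(r_out_vox[a]))
  offs <- as.matrix(expand.grid(ranges))
  q_in <- rowSums(sweep(offs, 2, r_in_vox, `/`)^2)
  q_out <- rowSums(sweep(offs, 2, r_out_vox, `/`)^2)
  ball <- q_in <= 1
  shell <- !ball & q_out <= 1
  ball_offs <- offs[ball, , drop = FALSE]
  shell_offs <- offs[shell, , drop = FALSE]
  # small ball (1 scale) for the peak measurement
  peak_ball <- offs[rowSums(sweep(offs, 2, scale_um / vs, `/`)^2) <= 1, ,
                    drop = FALSE]

  n <- nrow(centers_idx)
  integrated <- numeric(n)
  peak <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- round(centers_idx[i, ])
    vals_at <- function(om) {
      pts <- sweep(om, 2, c0, `+`)
      ok <- rep(TRUE, nrow(pts))
      for (a in seq_len(nd)) ok <- ok & pts[, a] >= 1 & pts[, a] <= d[a]
      data[pts[ok, , drop = FALSE]]
    }
    ball_v <- vals_at(ball_offs)
    shell_v <- vals_at(shell_offs)
    bg <- if (length(shell_v)) median(shell_v) else 0
    integrated[i] <- sum(ball_v) - bg * length(ball_v)
    pk <- vals_at(peak_ball)
    peak[i] <- if (length(pk)) max(pk) - bg else NA_real_
  }
  list(integrated = integrated, peak = peak)
}

#' Filter a spot table by integrated intensity
#'
#' Strict inequality (`integrated_intensity > min_intensity`), matching the
#' printed gating rules (">25,000", "more than 2000", "greater than
#' 50,000"). The input table is untouched; the gate value is recorded on
#' the result for provenance.
#'
#' @param spots a [spot_table()].
#' @param min_intensity gate in ADU.
#' @return the gated [spot_table()] with attribute `intensity_gate`.
#' @export
gate_by_intensity <- function(spots, min_intensity) {
  spots <- spot_table(spots)
  out <- spots[spots$integrated_intensity > min_intensity, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spot_table", "data.frame")
  attr(out, "intensity_gate") <- min_intensity
  out
}

#' Embryo inclusion decision from a spot count
#'
#' The assays use different inclusion rules: the proximity assay requires a
#' minimum of 25 translation spots (inclusive, `strict = FALSE`), the
#' overlap assay more than 3 (strict) and the re-localization assay more
#' than 7 (strict).
#'
#' @param n_spots spot count(s) after gating.
#' @param min_count rule threshold.
#' @param strict if `TRUE` the rule is `n > min_count`, else `n >= min_count`.
#' @return logical vector with attribute `rule` (human-readable).
#' @export
embryo_inclusion <- function(n_spots, min_count, strict = FALSE) {
  dec <- if (strict) n_spots > min_count else n_spots >= min_count
  attr(dec, "rule") <- paste0(if (strict) "> " else ">= ", min_count, " spots")
  dec
}
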