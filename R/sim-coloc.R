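#' Parameters for a synthetic two-channel colocalization scene
#'
#' Emulates dual-probe single-molecule FISH / translation-spot imaging: true
#' mRNA spots are placed inside cells; with probability
#' `true_overlap_fraction` an mRNA carries a partner spot in the other
#' channel (offset by a uniform jitter up to `max_pairing_offset_um`), and
#' each channel independently renders a true spot with its
#' `detection_efficiency`.
#'
#' @param n_mrna number of true mRNA spots.
#' @param true_overlap_fraction probability an mRNA spot carries a partner.
#' @param detection_efficiency length-2 probabilities that a true spot is
#'   rendered in (channel 1 = partner/translation, channel 2 = mRNA).
#' @param max_pairing_offset_um maximum centre offset between paired spots.
#' @param intensity_law lognormal peak-amplitude law shared by both channels.
#' @param psf_sigma_um rendering sigma (z,y,x) um.
#' @param background_level constant offset (ADU).
#' @param noise `NULL` or `list(gain =, read_sd =)`.
#' @param seed integer seed.
#' @return a `coloc_params` list.
#' @export
coloc_params <- function(n_mrna = 300L,
                         true_overlap_fraction = 0.6,
                         detection_efficiency = c(1, 1),
                         max_pairing_offset_um = 0.1,
                         intensity_law = list(median = 800, sdlog = 0.3),
                         psf_sigma_um = c(0.35, 0.15, 0.15),
                         background_level = 20,
                         noise = NULL,
                         seed = 1L) {
  p <- c(true_overlap_fraction, detection_efficiency)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0,1]")
  if (length(detection_efficiency) != 2L) {
    stop("detection_efficiency must have one value per channel")
  }
  if (max_pairing_offset_um < 0) stop("max_pairing_offset_um must be >= 0")
  structure(list(n_mrna = as.integer(n_mrna),
                 true_overlap_fraction = true_overlap_fraction,
                 detection_efficiency = detection_efficiency,
                 max_pairing_offset_um = max_pairing_offset_um,
                 intensity_law = intensity_law, psf_sigma_um = psf_sigma_um,
                 background_level = background_level, noise = noise,
                 seed = as.integer(seed)),
            class = "coloc_params")
}

#' Generate a paired two-channel spot scene with ground truth
#'
#' @param labels a [label_volume()] giving the cells spots may occupy.
#' @param params a [coloc_params()].
#' @return list with `channel1`/`channel2` ([image_stack()]s), `table1`/
#'   `table2` ([spot_table()]s of the rendered ground-truth spots, usable
#'   directly by [match_spots()]), and `truth` (list: `mrna` positions,
#'   `paired` logical, `rendered1`, `rendered2`, `pairings` data frame of
#'   rendered-pair ids).
#' @export
generate_coloc_pair <- function(labels, params) {
  stopifnot(inherits(labels, "label_volume"), inherits(params, "coloc_params"))
  vs <- labels$voxel_size
  d <- dim(labels$labels)
  inside <- labels$labels > 0L

  sim <- withr::with_seed(params$seed, {
    pos2 <- sample_uniform_in_cells(params$n_mrna, inside, labels)
    paired <- runif(params$n_mrna) < params$true_overlap_fraction
    # uniform jitter in a sphere of radius max_pairing_offset_um
    jit <- matrix(rnorm(3 * params$n_mrna), ncol = 3)
    jn <- sqrt(rowSums(jit^2))
    jn[jn == 0] <- 1
    rad <- params$max_pairing_offset_um * runif(params$n_mrna)^(1 / 3)
    jit <- jit / jn * rad
    pos1 <- pos2 + jit
    extent <- (d - 1) * vs
    pos1 <- pmin(pmax(pos1, 0), matrix(rep(extent, each = params$n_mrna),
                                       ncol = 3))
    rendered1 <- paired & runif(params$n_mrna) < params$detection_efficiency[1]
    rendered2 <- runif(params$n_mrna) < params$detection_efficiency[2]
    amp1 <- rlnorm(params$n_mrna, log(params$intensity_law$median),
                   params$intensity_law$sdlog)
    amp2 <- rlnorm(params$n_mrna, log(params$intensity_law$median),
                   params$intensity_law$sdlog)
    list(pos1 = pos1, pos2 = pos2, paired = paired,
         rendered1 = rendered1, rendered2 = rendered2,
         amp1 = amp1, amp2 = amp2)
  })

  ch1 <- render_gaussian_spots(d, vs, sim$pos1[sim$rendered1, , drop = FALSE],
                               sim$amp1[sim$rendered1], params$psf_sigma_um) +
    params$background_level
  ch2 <- render_gaussian_spots(d, vs, sim$pos2[sim$rendered2, , drop = FALSE],
                               sim$amp2[sim$rendered2], params$psf_sigma_um) +
    params$background_level
  if (!is.null(params$noise)) {
    ch1 <- withr::with_seed(params$seed + 1L, apply_camera_noise(ch1, params$noise))
    ch2 <- withr::with_seed(params$seed + 2L, apply_camera_noise(ch2, params$noise))
  }

  tab <- function(pos, amp, rendered, channel, sig) {
    keep <- which(rendered)
    # integrated intensity of a 3D Gaussian of peak `amp`, in ADU-voxel units
    vol <- prod(sig / vs) * (2 * pi)^(3 / 2)
    spot_table(data.frame(
      id = keep, channel = rep(channel, length(keep)),
      z_um = pos[keep, 1], y_um = pos[keep, 2], x_um = pos[keep, 3],
      peak_intensity = amp[keep], integrated_intensity = amp[keep] * vol,
      category = rep("unassigned", length(keep)),
      membrane_distance_um = rep(NA_real_, length(keep)),
      stringsAsFactors = FALSE
    ))
  }
  pairings <- data.frame(
    id1 = which(sim$paired & sim$rendered1 & sim$rendered2),
    id2 = which(sim$paired & sim$rendered1 & sim$rendered2)
  )
  list(
    channel1 = image_stack(ch1, vs), channel2 = image_stack(ch2, vs),
    table1 = tab(sim$pos1, sim$amp1, sim$rendered1, "ch1", params$psf_sigma_um),
    table2 = tab(sim$pos2, sim$amp2, sim$rendered2, "ch2", params$psf_sigma_um),
    truth = list(mrna_um = sim$pos2, paired = sim$paired,
                 rendered1 = sim$rendered1, rendered2 = sim$rendered2,
                 pairings = pairings)
  )
}

sample_uniform_in_cells <- function(n, inside, labels) {
  vs <- labels$voxel_size
  d <- dim(inside)
  vox <- which(inside)
  pick <- vox[sample.int(length(vox), n, replace = TRUE)]
  co <- arrayInd(pick, d) + matrix(runif(3 * n, -0.5, 0.5), n, 3)
  co <- pmin(pmax(co, 1), matrix(rep(d, each = n), n, 3))
  sweep(co - 1, 2, vs, `*`)
}
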