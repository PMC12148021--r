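#' Parameters for a simulated FRAP experiment
#'
#' Emulates the acquisition used for apical membrane FRAP: pre-bleach frames
#' at steady intensity, a bleach event at t = 0 removing `bleach_depth` of
#' the signal in the bleached region, single-exponential recovery of the
#' mobile fraction, multiplicative acquisition photobleaching applied to
#' every acquired frame, plus a constant background and optional Gaussian
#' read noise.
#'
#' @param mobile_fraction fraction of the bleached signal that recovers,
#'   in [0,1].
#' @param half_time_s recovery half-time in seconds.
#' @param bleach_depth fraction of the pre-bleach signal removed at t = 0.
#' @param acquisition_bleach_rate per-frame multiplicative decay (1 = none).
#' @param signal_level pre-bleach intensity of both regions (ADU).
#' @param background_level constant background (ADU).
#' @param frame_interval_s acquisition interval, default 20 s.
#' @param n_prebleach_frames pre-bleach frames, default 5.
#' @param duration_s post-bleach duration, default 1200 s (20 min).
#' @param noise_sd Gaussian noise sd (ADU), 0 = off.
#' @param seed integer seed.
#' @return a `frap_sim_params` list.
#' @export
frap_sim_params <- function(mobile_fraction = 0.6,
                            half_time_s = 120,
                            bleach_depth = 0.7,
                            acquisition_bleach_rate = 0.9975,
                            signal_level = 1000,
                            background_level = 100,
                            frame_interval_s = 20,
                            n_prebleach_frames = 5L,
                            duration_s = 1200,
                            noise_sd = 0,
                            seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("mobile_fraction must be in [0,1]")
  }
  if (half_time_s <= 0) stop("half_time_s must be positive")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  if (duration_s < frame_interval_s) {
    stop("duration_s must be at least one frame interval")
  }
  if (bleach_depth < 0 || bleach_depth > 1) stop("bleach_depth must be in [0,1]")
  structure(list(mobile_fraction = mobile_fraction, half_time_s = half_time_s,
                 bleach_depth = bleach_depth,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 signal_level = signal_level,
                 background_level = background_level,
                 frame_interval_s = frame_interval_s,
                 n_prebleach_frames = as.integer(n_prebleach_frames),
                 duration_s = duration_s, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "frap_sim_params")
}

#' Simulate a FRAP trace with ground truth
#'
#' The true bleached-region intensity is
#' `I(t) = I0 * (1 - depth) + I0 * depth * R(t)` with
#' `R(t) = M * (1 - exp(-t * ln 2 / t_half))` for t >= 0 and `I(t) = I0`
#' before the bleach. Every acquired frame (bleached and reference regions)
#' is multiplied by `acquisition_bleach_rate^frame_index`, offset by the
#' background, and optionally corrupted by Gaussian noise. The ground truth
#' records the noiseless recovery `R(t)` and the corrected series the
#' correction chain should reproduce (`depth * R(t)` after the bleach, i.e.
#' recovery normalized against pre-bleach values).
#'
#' @param params a [frap_sim_params()].
#' @return list with `trace` (a raw [frap_trace()]) and `truth` (data frame:
#'   time_s, recovery_true, corrected_expected).
#' @export
simulate_frap <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  dt <- params$frame_interval_s
  n_pre <- params$n_prebleach_frames
  t_post <- seq(0, params$duration_s, by = dt)
  time_s <- c(-(n_pre:1) * dt, t_post)
  n <- length(time_s)
  frame_idx <- seq_len(n) - 1L

  recovery <- ifelse(
    time_s < 0, NA_real_,
    params$mobile_fraction *
      (1 - exp(-pmax(time_s, 0) * log(2) / params$half_time_s))
  )
  I0 <- params$signal_level
  true_bleached <- ifelse(
    time_s < 0, I0,
    I0 * (1 - params$bleach_depth) + I0 * params$bleach_depth * recovery
  )
  decay <- params$acquisition_bleach_rate^frame_idx
  bleached <- true_bleached * decay + params$background_level
  reference <- I0 * decay + params$background_level
  background <- rep(params$background_level, n)
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(params$seed,
                              rnorm(3 * n, 0, params$noise_sd))
    bleached <- bleached + noise[seq_len(n)]
    reference <- reference + noise[n + seq_len(n)]
    background <- background + noise[2 * n + seq_len(n)]
  }
  trace <- frap_trace(time_s = time_s, bleached = bleached,
                      reference = reference, background = background,
                      n_prebleach = n_pre)
  truth <- data.frame(
    time_s = time_s,
    recovery_true = recovery,
    corrected_expected = ifelse(time_s < 0, params$bleach_depth,
                                params$bleach_depth * recovery)
  )
  list(trace = trace, truth = truth, params = params)
}
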