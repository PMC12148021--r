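#' FRAP trace container
#'
#' Time-indexed intensities of the bleached region, a non-bleached apical
#' reference region, and an outside background region. `n_prebleach` frames
#' precede the bleach; the first post-bleach frame defines t = 0. The
#' `corrected` series (unitless recovery) is filled by [correct_trace()].
#'
#' @param time_s strictly increasing times in seconds (negative before the
#'   bleach, 0 at the first post-bleach frame).
#' @param bleached,reference,background intensities (ADU) per frame;
#'   `background` may be a scalar.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @return a `frap_trace` (list) with attribute `n_prebleach`.
#' @export
frap_trace <- function(time_s, bleached, reference, background,
                       n_prebleach = 5L) {
  n <- length(time_s)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n_prebleach >= n) {
    stop("need 1 <= n_prebleach < number of frames")
  }
  if (length(bleached) != n || length(reference) != n) {
    stop("bleached/reference must align with time")
  }
  background <- rep_len(background, n)
  if (abs(time_s[n_prebleach + 1L]) > 1e-9) {
    stop("the first post-bleach frame must be at t = 0")
  }
  structure(list(time_s = time_s, bleached = bleached, reference = reference,
                 background = background, corrected = NULL),
            class = "frap_trace", n_prebleach = n_prebleach)
}

#' FRAP correction and normalization chain
#'
#' Per frame i: (1) background subtraction, `b_i = bleached_i - bg_i`,
#' `r_i = reference_i - bg_i`; (2) acquisition-photobleaching correction
#' from the reference region, `c_i = r_i / mean(r over the pre-bleach
#' frames)` and `B_i = b_i / c_i`; (3) zero baseline: the corrected
#' intensity at the first post-bleach frame (t = 0) is subtracted; (4)
#' normalization of the change against pre-bleach values:
#' `recovery_i = (B_i - B_t0) / mean(B over the pre-bleach frames)`.
#' The corrected value at t = 0 is exactly 0 by construction, and the
#' chain is invariant to a global intensity gain. With
#' `normalization = "bleached_amount"` the change is instead divided by
#' `mean(B_pre) - B_t0`, so the curve plateaus at the mobile fraction.
#'
#' @param trace a [frap_trace()].
#' @param normalization `"prebleach"` (default, as the assay defines it) or
#'   `"bleached_amount"`.
#' @return the trace with `corrected` filled and attributes
#'   `prebleach_mean` (mean corrected pre-bleach intensity), `b_t0` and
#'   `bleach_depth_est` (`1 - b_t0 / prebleach_mean`).
#' @export
correct_trace <- function(trace, normalization = c("prebleach",
                                                   "bleached_amount")) {
  stopifnot(inherits(trace, "frap_trace"))
  normalization <- match.arg(normalization)
  n_pre <- attr(trace, "n_prebleach")
  pre <- seq_len(n_pre)
  t0 <- n_pre + 1L
  b <- trace$bleached - trace$background
  r <- trace$reference - trace$background
  r_pre <- mean(r[pre])
  if (r_pre <= 0) stop("invalid trace: non-positive pre-bleach reference")
  cf <- r / r_pre
  if (any(cf <= 0)) stop("invalid trace: non-positive correction factor")
  B <- b / cf
  B_pre <- mean(B[pre])
  if (B_pre <= 0) stop("invalid trace: non-positive pre-bleach intensity")
  denom <- switch(normalization,
                  prebleach = B_pre,
                  bleached_amount = B_pre - B[t0])
  if (denom <= 0) stop("invalid trace: bleached amount not positive")
  trace$corrected <- (B - B[t0]) / denom
  attr(trace, "prebleach_mean") <- B_pre
  attr(trace, "b_t0") <- B[t0]
  attr(trace, "bleach_depth_est") <- 1 - B[t0] / B_pre
  attr(trace, "normalization") <- normalization
  trace
}

#' Average corrected FRAP traces of one animal
#'
#' Frame-wise mean of the corrected series of `per_animal` measurements
#' (two per animal in the assay). Traces must share the time grid exactly;
#' resampling is refused.
#'
#' @param traces list of corrected [frap_trace()]s.
#' @param per_animal required number of traces (default 2).
#' @return a [frap_trace()] with averaged series.
#' @export
average_animal <- function(traces, per_animal = 2L) {
  if (length(traces) != per_animal) {
    stop("expected ", per_animal, " traces per animal, got ", length(traces))
  }
  t0 <- traces[[1]]
  for (tr in traces) {
    stopifnot(inherits(tr, "frap_trace"))
    if (is.null(tr$corrected)) stop("traces must be corrected first")
    if (!isTRUE(all.equal(tr$time_s, t0$time_s)) ||
        attr(tr, "n_prebleach") != attr(t0, "n_prebleach")) {
      stop("traces do not share a time grid; resampling is not supported")
    }
  }
  avg <- function(f) rowMeans(vapply(traces, `[[`, numeric(length(t0$time_s)), f))
  out <- frap_trace(t0$time_s, avg("bleached"), avg("reference"),
                    avg("background"), attr(t0, "n_prebleach"))
  out$corrected <- avg("corrected")
  attr(out, "prebleach_mean") <- mean(vapply(traces, attr, numeric(1),
                                             "prebleach_mean"))
  attr(out, "bleach_depth_est") <- mean(vapply(traces, attr, numeric(1),
                                               "bleach_depth_est"))
  out
}

#' Fit a single-exponential recovery to a corrected FRAP trace
#'
#' Least-squares fit of `F(t) = M * (1 - exp(-t * ln 2 / t_half))` to the
#' post-bleach corrected series rescaled by the estimated bleach depth, so
#' `M` is the standard mobile fraction (the fraction of the bleached signal
#' that recovers). Bounded (`M` in [0, 1.5], `t_half` > 0) with multi-start
#' initialization over a half-time grid. With `M` near zero the half-time
#' is unidentifiable and flagged.
#'
#' @param trace a corrected [frap_trace()] with at least 10 post-bleach
#'   frames.
#' @param min_post_frames minimum post-bleach frames (default 10).
#' @return list with `mobile_fraction`, `half_time_s`,
#'   `half_time_identifiable`, `converged`, `rss`, and the `fit` object.
#' @export
fit_recovery <- function(trace, min_post_frames = 10L) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$corrected)) stop("run correct_trace() first")
  n_pre <- attr(trace, "n_prebleach")
  post <- (n_pre + 1L):length(trace$time_s)
  if (length(post) < min_post_frames) {
    stop("need at least ", min_post_frames, " post-bleach frames")
  }
  t <- trace$time_s[post]
  depth <- attr(trace, "bleach_depth_est")
  if (identical(attr(trace, "normalization"), "bleached_amount")) depth <- 1
  if (!is.finite(depth) || depth <= 0.01) {
    stop("estimated bleach depth too small to normalize the recovery")
  }
  y <- trace$corrected[post] / depth
  t_max <- max(t)
  # coarse grid solution: extra multi-start anchor, and the fallback when
  # the gradient-based fits all fail (degenerate M ~ 0 traces)
  grid <- expand.grid(M = seq(0, 1.5, by = 0.05),
                      th = exp(seq(log(0.02 * t_max), log(2 * t_max),
                                   length.out = 25)))
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    sum((y - grid$M[i] * (1 - exp(-t * log(2) / grid$th[i])))^2)
  }, numeric(1))
  g_best <- grid[which.min(rss_grid), ]
  starts <- rbind(expand.grid(M = c(0.3, 0.6, 0.9),
                              th = t_max * c(0.05, 0.1, 0.25, 0.5, 1)),
                  data.frame(M = max(g_best$M, 1e-3), th = g_best$th))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ M * (1 - exp(-t * log(2) / th)),
        start = list(M = starts$M[i], th = starts$th[i]),
        lower = c(M = 0, th = 1e-6), upper = c(M = 1.5, th = 100 * t_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # gradient fits failed everywhere (flat trace); report the grid optimum
    return(list(mobile_fraction = g_best$M, half_time_s = g_best$th,
                half_time_identifiable = FALSE, converged = TRUE,
                rss = min(rss_grid), fit = NULL))
  }
  cf <- coef(best$fit)
  m_hat <- unname(cf["M"])
  list(mobile_fraction = m_hat,
       half_time_s = unname(cf["th"]),
       half_time_identifiable = m_hat > 0.02,
       converged = TRUE, rss = best$rss, fit = best$fit)
}
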