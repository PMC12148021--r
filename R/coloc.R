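#' Match spots across two channels (object-based colocalization)
#'
#' Iterated mutual-nearest-neighbour matching within a physical radius:
#' in each round, every unmatched spot pair that are each other's nearest
#' unmatched neighbour and lie within `radius_um` is accepted; rounds repeat
#' until no pair is added. Conflicts resolve by ascending offset with a
#' deterministic `(offset, id_a, id_b)` tie-break. Matching uses 3D
#' distances when both tables carry z, else 2D.
#'
#' @param table_a,table_b [spot_table()]s in the same coordinate frame.
#' @param radius_um maximum centre-to-centre offset (>= 0).
#' @return a `match_result`: list with `pairs` (data frame id_a, id_b,
#'   offset_um), `n_a`, `n_b`, `n_matched`, `overlap_fraction_a`
#'   (= n_matched / n_a), `overlap_fraction_b`, `match_radius_um`.
#' @export
match_spots <- function(table_a, table_b, radius_um) {
  if (radius_um < 0) stop("radius_um must be nonnegative")
  table_a <- spot_table(table_a)
  table_b <- spot_table(table_b)
  n_a <- nrow(table_a)
  n_b <- nrow(table_b)
  pairs <- data.frame(id_a = integer(0), id_b = integer(0),
                      offset_um = numeric(0))
  if (n_a > 0L && n_b > 0L) {
    use_z <- !anyNA(table_a$z_um) && !anyNA(table_b$z_um)
    pa <- if (use_z) cbind(table_a$z_um, table_a$y_um, table_a$x_um) else
      cbind(table_a$y_um, table_a$x_um)
    pb <- if (use_z) cbind(table_b$z_um, table_b$y_um, table_b$x_um) else
      cbind(table_b$y_um, table_b$x_um)
    dm2 <- 0
    for (a in seq_len(ncol(pa))) {
      dm2 <- dm2 + outer(pa[, a], pb[, a], `-`)^2
    }
    dm <- sqrt(dm2)
    free_a <- rep(TRUE, n_a)
    free_b <- rep(TRUE, n_b)
    repeat {
      if (!any(free_a) || !any(free_b)) break
      sub <- dm[free_a, free_b, drop = FALSE]
      ia <- which(free_a)
      ib <- which(free_b)
      nn_b <- apply(sub, 1, which.min)
      nn_a <- apply(sub, 2, which.min)
      mutual <- which(nn_a[nn_b] == seq_along(ia))
      if (!length(mutual)) break
      off <- sub[cbind(mutual, nn_b[mutual])]
      ok <- off <= radius_um
      if (!any(ok)) break
      mutual <- mutual[ok]
      off <- off[ok]
      ord <- order(off, table_a$id[ia[mutual]],
                   table_b$id[ib[nn_b[mutual]]])
      mutual <- mutual[ord]
      off <- off[ord]
      pairs <- rbind(pairs, data.frame(
        id_a = table_a$id[ia[mutual]],
        id_b = table_b$id[ib[nn_b[mutual]]],
        offset_um = off
      ))
      free_a[ia[mutual]] <- FALSE
      free_b[ib[nn_b[mutual]]] <- FALSE
    }
  }
  structure(list(pairs = pairs, n_a = n_a, n_b = n_b,
                 n_matched = nrow(pairs),
                 overlap_fraction_a = if (n_a) nrow(pairs) / n_a else NA_real_,
                 overlap_fraction_b = if (n_b) nrow(pairs) / n_b else NA_real_,
                 match_radius_um = radius_um),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$n_matched, " pairs of ", x$n_a, " x ", x$n_b,
      " spots within ", x$match_radius_um, " um (fractions ",
      sprintf("%.3f / %.3f", x$overlap_fraction_a, x$overlap_fraction_b),
      ")\n", sep = "")
  invisible(x)
}

#' Translation-spot / mRNA overlap fraction for one embryo
#'
#' Gates the GFP table at the translation gate (> 25,000 ADU by default),
#' applies the inclusion rule (more than 3 translation spots, strict), and
#' reports the asymmetric overlap: matched translation spots divided by all
#' translation spots.
#'
#' @param translation_spots GFP-channel [spot_table()] (ungated).
#' @param mrna_spots mRNA-channel [spot_table()].
#' @param config a [run_config()]; uses `gate_translation_overlap`,
#'   `min_spots_overlap`, `match_radius_um`.
#' @return list with `included`, `n_translation`, `n_matched`,
#'   `overlap_fraction` (NA when excluded) and the underlying
#'   `match_result` (NULL when excluded).
#' @export
translation_overlap <- function(translation_spots, mrna_spots,
                                config = run_config()) {
  gated <- gate_by_intensity(translation_spots, config$gate_translation_overlap)
  inc <- embryo_inclusion(nrow(gated), config$min_spots_overlap, strict = TRUE)
  if (!inc) {
    return(list(included = FALSE, n_translation = nrow(gated),
                n_matched = NA_integer_, overlap_fraction = NA_real_,
                match = NULL, rule = attr(inc, "rule")))
  }
  m <- match_spots(gated, mrna_spots, config$match_radius_um)
  list(included = TRUE, n_translation = m$n_a, n_matched = m$n_matched,
       overlap_fraction = m$overlap_fraction_a, match = m,
       rule = attr(inc, "rule"))
}

#' Probe-binding efficiency from a dual-probe experiment
#'
#' Two primary probe sets against the same mRNA, imaged in different
#' channels: after gating both tables at the mRNA gate (> 50,000 ADU by
#' default), the overlapping spot count divided by each channel's total
#' gives that channel's probe-binding efficiency.
#'
#' @param table_p1,table_p2 per-probe [spot_table()]s (ungated).
#' @param config a [run_config()]; uses `gate_mrna`, `match_radius_um`.
#' @return list with `efficiency` (named length-2: channel1, channel2),
#'   `n1`, `n2`, `n_matched`, `match`, and `flag` (character, e.g. an empty
#'   channel makes the corresponding efficiency undefined).
#' @export
probe_efficiency <- function(table_p1, table_p2, config = run_config()) {
  g1 <- gate_by_intensity(table_p1, config$gate_mrna)
  g2 <- gate_by_intensity(table_p2, config$gate_mrna)
  flag <- character(0)
  if (nrow(g1) == 0L) flag <- c(flag, "channel 1 empty: efficiency undefined")
  if (nrow(g2) == 0L) flag <- c(flag, "channel 2 empty: efficiency undefined")
  m <- match_spots(g1, g2, config$match_radius_um)
  eff <- c(channel1 = if (nrow(g1)) m$n_matched / nrow(g1) else NA_real_,
           channel2 = if (nrow(g2)) m$n_matched / nrow(g2) else NA_real_)
  list(efficiency = eff, n1 = nrow(g1), n2 = nrow(g2),
       n_matched = m$n_matched, match = m, flag = flag)
}
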